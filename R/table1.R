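#' Structural characteristics of the 31 putative LPMOs of the source study
#'
#' The published per-protein characteristics table of the metagenomic
#' AA10 cohort: phylogenetic group, full and mature lengths, positions of
#' the second histidine (Hx) and the conserved aromatic (Fy) of the
#' H1-Hx-Fy motif in mature numbering, and cysteine counts in the
#' full-length protein and within the catalytic domain. This table is the
#' input specification for the bundled synthetic stand-in cohort (see
#' [make_table1_cohort()]) and the ground truth that annotation results
#' are compared against.
#'
#' @return A `data.frame` with columns `group`, `id`, `full_length`,
#'   `mature_length`, `hx`, `fy`, `cys_full`, `cys_catalytic`.
#' @export
lpmo_table1 <- function() {
  txt <- "group id full mature hx fy cf cc
1 GL0247266 631 604 112 185 4 4
1 GL1034380 284 240 156 227 4 3
1 GL0125011 510 481 118 189 6 4
1 GL0658692 389 365 104 174 8 6
1 GL0213284 388 364 104 174 8 6
2 GL0393374 211 201 111 191 1 1
2 GL0681738 211 201 111 191 1 1
2 GL0089352 211 201 111 191 1 1
3.1 GL0183513 478 448 87 162 6 4
3.1 GL0251010 483 456 88 170 6 4
3.1 GL0522565 488 457 126 169 6 4
3.1 GL0422153 493 456 92 169 6 4
3.2 GL1004230 279 211 106 187 4 4
3.2 GL0883009 370 349 99 182 2 1
3.2 GL0293304 457 443 100 181 1 0
3.3 GL0656018 451 419 90 161 2 2
3.3 GL0225724 220 193 99 170 0 0
3.3 GL0391320 599 574 97 168 8 0
3.3 GL0200824 600 575 97 168 7 0
3.3 GL0338092 600 575 97 168 8 0
3.3 GL0600730 197 171 87 160 4 4
3.4 GL0066553 499 449 87 160 6 4
3.4 GL0555809 474 451 87 159 6 4
3.4 GL0999597 258 238 93 167 4 4
3.5 GL0620585 583 562 104 189 4 2
3.6 GL0297948 484 464 88 160 6 4
3.6 GL0875000 485 465 88 160 6 4
3.6 GL0489328 486 466 88 160 6 4
3.6 GL0507050 486 466 88 160 6 4
3.6 GL0417116 483 463 88 160 6 4
3.6 GL0772141 482 462 88 160 6 4"
  tab <- utils::read.table(text = txt, header = TRUE,
                           colClasses = c("character", "character",
                                          rep("integer", 6)),
                           stringsAsFactors = FALSE)
  names(tab) <- c("group", "id", "full_length", "mature_length",
                  "hx", "fy", "cys_full", "cys_catalytic")
  tab
}
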