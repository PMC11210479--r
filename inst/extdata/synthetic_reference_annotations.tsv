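ref_id	sequence	hx	fy	diagnostic_pos	triad	alanine_anchor	substrate
REF_CHITIN	HGAMESPTDRNARDVRDRKVIMLARKTTQIVDDDKLRAIVWRRLYSVQGIETTGKAFPPTMGTGGILYGEWDLLIVPVTPWYQPYALGVWFGYEPSQTAHAIDGWSGKLNPVMSDTEGFQKGIQAYEPQSVEMWGIQVRQNADNDQYAGTKPEFPQGNETWKSPWLDIADTGNAFYGQTPDKGSTYNFTTFILMMKFNPR	100	175	168	105,161,165	125	chitin
REF_CELLULOSE	HGAMESPTDRNAWEMFSWDMNVPLFYRDVAWVTWLMFTYLPMFFYFPKKLYENDNSLSYQLKWRIEFGRWPSPAYNSRITITNGYYPTWQMVFLDKDGNTDAVAQGSTAHAIDGWSGKLNPVMSDTEGFQKGIQAYEPQSVETAMRTMMPPNQTAQDNQTSQKWMFGNETWKSPWLDRADTGNAFYGQTPDKGSPMRRLGRKSIIPISTW	110	185	178	115,171,175	135	cellulose
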