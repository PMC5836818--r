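!Series_title "synthetic demonstration cohort (not real array data)"
!Series_summary "Hand-written log2 expression fixture in GEO Series Matrix layout"
!series_matrix_table_begin
"ID_REF"	"SAMPLE_01"	"SAMPLE_02"	"SAMPLE_03"	"SAMPLE_04"
"200001_at"	8.412000	9.103000	7.954000	8.677000
"200002_s_at"	7.105000	7.884000	6.932000	7.410000
"200003_at"	9.210000	8.655000	9.478000	9.002000
"200004_x_at"	6.240000	6.810000	6.055000	6.500000
"200005_at"	4.120000	4.480000	3.905000	4.233000
!series_matrix_table_end
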