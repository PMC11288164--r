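study	category	count	body_site
hmp_prjna43021	mag	2820	NA
ehomd_v10	mag	8622	NA
hrgm_catalog	mag	6185	NA
cultivated_gut_refs	pure_culture_genome	3324	NA
gut_biobank_prjna656402	pure_culture_genome	97	NA
gut_culture_prjeb10915	pure_culture_genome	216	NA
human_oral_v1	mag	452	NA
uhgg_prjeb33885	mag	4579	NA
ihmp_assembled	assembled_metagenome	558	NA
gut_reads_study1	read_metagenome	107	gut
gut_reads_study2	read_metagenome	162	gut
gut_reads_study3	read_metagenome	9	gut
gut_reads_study4	read_metagenome	234	gut
oral_reads_study4	read_metagenome	295	oral
lung_reads_study5	read_metagenome	38	lung
lung_reads_study6	read_metagenome	47	lung
lung_reads_study7	read_metagenome	18	lung
gut_reads_study8	read_metagenome	128	gut
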