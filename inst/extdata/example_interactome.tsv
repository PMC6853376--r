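# small synthetic miRNA-RNA interactome (seeded generator output)
rna_id	mirna_id	binding_mode
RNA0001	miR004	seed-nc
RNA0023	miR004	seed-nc
RNA0001	miR006	seed-nc
RNA0013	miR004	seed-nc
RNA0025	miR003	seed-nc
RNA0024	miR004	kmer
RNA0006	miR006	seed-nc
RNA0025	miR004	seed-nc
RNA0024	miR005	seed-nc
RNA0001	miR003	seed-nc
RNA0008	miR003	seed-nc
RNA0015	miR002	seed-nc
RNA0023	miR002	seed-nc
RNA0024	miR003	seed-nc
RNA0014	miR003	seed-nc
RNA0017	miR003	kmer
RNA0019	miR006	seed-nc
RNA0008	miR004	seed-nc
RNA0019	miR004	seed-nc
RNA0001	miR001	seed-nc
RNA0025	miR002	seed-nc
RNA0019	miR003	noseed-9nt
RNA0019	miR005	kmer
RNA0018	miR004	noseed-9nt
RNA0011	miR004	seed-nc
RNA0003	miR003	kmer
RNA0008	miR006	seed-nc
RNA0023	miR006	seed-nc
RNA0010	miR004	seed-nc
RNA0006	miR003	seed-nc
RNA0025	miR006	seed-nc
RNA0025	miR005	seed-nc
RNA0021	miR004	seed-nc
RNA0001	miR005	noseed
RNA0006	miR004	seed-nc
RNA0001	miR002	seed-nc
RNA0013	miR005	seed-nc
RNA0008	miR005	seed-nc
RNA0015	miR004	seed-nc
RNA0009	miR006	seed-nc
RNA0017	miR006	seed-nc
RNA0007	miR004	seed-nc
RNA0020	miR004	seed-nc
RNA0009	miR002	kmer
RNA0023	miR005	noseed
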