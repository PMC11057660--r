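v_gene,j_gene,cdr3_aa,source
TRBV26,TRBJ2-7,CLSRKLATVDDAEF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV2,TRBJ1-5,CWPGSPQTGCAYF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV17,TRBJ1-2,CGDGTTRWEAHEQTF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV13-1,TRBJ1-2,CEIGKILGKIQKWF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV3,TRBJ2-5,CTQLKLLTSEANF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV3,TRBJ2-5,CFEIRWWQHHFDAGREF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV17,TRBJ1-3,CWYTRDIYMVCMNKVF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV13-2,TRBJ2-7,CCSGQWPMYHGILAPF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV4,TRBJ2-3,CWLLCQSAIRFKFF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV1,TRBJ2-1,CGFNSKGHNVKCLCF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV16,TRBJ1-4,CNFPFKVNWHYHF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV19,TRBJ1-5,CPAYSIMAIALF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV13-1,TRBJ2-1,CLVPWMWFEYALSWVPAKF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV1,TRBJ1-1,CTCEIAGADFCDF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV26,TRBJ2-1,CYWHWIVPENF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV15,TRBJ1-5,CHDIMCKADHF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV17,TRBJ2-2,CIILPNQRGVWAPF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV14,TRBJ2-4,CRVHTWPMIGAF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV14,TRBJ1-1,CWFRGRVHIWHDNVMF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV16,TRBJ1-4,CEQVRNRCYACRTQF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV14,TRBJ2-4,CCIFEGTCTWTF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV23,TRBJ2-5,CHPAFNGDRSYMETKIF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV4,TRBJ2-5,CCAMKDHTEHEFGSIF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV5,TRBJ2-3,CNDQNMILGASYF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV15,TRBJ2-5,CFDVAVKTEPVCPF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV26,TRBJ1-5,CWWGKPTYRDWCF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV26,TRBJ2-1,CFKTVGDFTSGFTF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV20,TRBJ1-1,CNTMGMGKIPDQWF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV12-2,TRBJ2-1,CDADYDPSHYNHF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV16,TRBJ1-4,CHYGWSDFQAKMF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV13-3,TRBJ2-4,CTEQNTHPHVLIF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV14,TRBJ2-2,CFWGCEEVWCIF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV4,TRBJ2-7,CSDTRAGRDDRGWLF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV5,TRBJ2-2,CDQPSGFIWFTIGVF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV13-2,TRBJ1-1,CCSILMHTMPMNSF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV31,TRBJ1-2,CLWLLLHWISDQF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV20,TRBJ1-3,CPVCSTETAIQLLCF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV31,TRBJ2-1,CEKYNCAAMDRF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV14,TRBJ2-7,CSERNERTCFMNF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV17,TRBJ2-2,CESGSHNTTWEF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV13-2,TRBJ2-3,CPWYNDSLF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV1,TRBJ1-1,CIAHPVAVSENKF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV20,TRBJ2-5,CKAVNNMFVLGQF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV1,TRBJ1-5,CRWDVTCFFCCPF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV17,TRBJ1-2,CFEVFGYRTRAYGF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV1,TRBJ1-2,CISVWNSYDVLASF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV1,TRBJ2-3,CESCQINKTMLMF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV14,TRBJ1-4,CWPDWCKNHERMEFF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV16,TRBJ1-2,CAYNGNVRDMWYRLPRF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV17,TRBJ1-1,CNNFLFYHYMF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV5,TRBJ2-2,CDDQDIKMRDRPF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV15,TRBJ2-2,CYWIMLQYSHTNRGF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV12-1,TRBJ2-7,CQWIYTEQCLWSF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV13-1,TRBJ1-4,CKVWMEDQGAITEF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV26,TRBJ2-5,CFPQTCVQHCYFINF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV12-2,TRBJ2-2,CVIGMHMWCMTFQPGF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV1,TRBJ1-4,CIRKKQPYPDEISNMCF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV20,TRBJ1-2,CFINFRKFAEMDFF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV2,TRBJ2-1,CVMLDELVLHSF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
TRBV13-1,TRBJ1-3,CPYNNNNMPF,"synthetic stand-in panel (simulated, not derived from any published antigen-specific TCR list)"
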