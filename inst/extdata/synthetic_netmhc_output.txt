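# NetMHC-style per-peptide output (synthetic example for the parser; the
# peptides and affinities below were made up by hand, not produced by any
# trained predictor)
# Input is in PEPTIDE format
----------------------------------------------------------------------------------------------------
 pos          HLA         peptide       Core Of Gp Gl Ip Il        Icore        Identity 1-log50k(aff) Affinity(nM)    %Rank  BindLevel
----------------------------------------------------------------------------------------------------
    0       H-2-Kb        SIINFEKL   SIINFEKL  0  0  0  0  0     SIINFEKL         PEPLIST         0.806        13.20     0.01 <= SB
    1       H-2-Kb        AAYAAAAL   AAYAAAAL  0  0  0  0  0     AAYAAAAL         PEPLIST         0.412       450.00     1.90 <= WB
    2       H-2-Kb        AAAAAAAL   AAAAAAAL  0  0  0  0  0     AAAAAAAL         PEPLIST         0.106     15830.00    32.00
    3       H-2-Kb       KAVYNFATM  KAVYNFAT  0  0  0  1  1    KAVYNFATM         PEPLIST         0.350       789.50     4.50
----------------------------------------------------------------------------------------------------
Protein PEPLIST. Allele H-2-Kb. Number of high binders 1. Number of weak binders 1. Number of peptides 4
----------------------------------------------------------------------------------------------------
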