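# Notes on the reference footprint fixture (table1_footprint.csv)

The fixture is a verbatim transcription of the published hydrogen-bond
persistence table for the two simulated TCR-pMHC complexes (complexes A and
B of the SB27-HLA-B*3508-LPEP crystal form). Empty persistence cells
correspond to the source's "(-)" ("no interaction observed in simulation").
Persistences are integer percent of simulation frames.

Known internal inconsistencies of the source, preserved verbatim and NOT
resolved by any code in this package:

1. "Gln7^O1^" (row pairing Gln7 with CDR3α Ser93^Oγ^, persistences 21/25)
   is almost certainly a typographical variant of Gln7^Oε1^; note that an
   earlier row already pairs Gln7^Nε2^ with the same Ser93^Oγ^ acceptor at
   different persistences (17/25). Both rows are kept as printed.
2. The accompanying figure legend describes Arg157 as "a short-lived
   contact only observed in the simulation of complex A", but the table
   records Arg157^Nη1/2^-Glu54^Oε1/2^ with persistence only in the
   Complex B column (27). The residue-level conservation report computed by
   `compare_footprints()` therefore flags Arg157 as B-only; reconciliation
   against the legend is left to the reader.
3. The same legend names "Arg162" among the complex-A-only long-lived
   contacts; no Arg162 row exists in the table (the table has Arg62, which
   IS complex-A-only and long-lived at 54%). The fixture follows the table.
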