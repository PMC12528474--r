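# Deposited data staging area

Two checks in the test suite recompute published quantities from the
deposited AIRR rearrangement tables (SRA BioProject PRJNA1194793; Zenodo
record 10.5281/zenodo.15584842). Those tables are not redistributable with
this package. To run the checks, download the archive and stage:

    data-raw/zenodo-15584842/mumt_proB.tsv   # muMT pro-B rearrangements
    data-raw/zenodo-15584842/proB.tsv        # wild-type pro-B rearrangements

Both files are AIRR-style TSV with at least `v_call` and `productive`
columns. Without them the corresponding test reports the data as missing.
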