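# occseq

Harvest occurrence-linked small-subunit (SSU) rRNA sequences.

## The problem

Biodiversity aggregators index hundreds of millions of *occurrences* —
documented instances of a taxon at a place and time — and an increasing
share of them, published from metagenomic surveys, link back to the
next-generation sequencing run that detected the organism. The sequence
data itself, however, sits in off-site archives as bulk FASTA/FASTQ files
of anonymous reads, with a separate MAPseq-style taxonomy-assignment
table mapping each read label to its classified lineage. A researcher who
wants "every SSU read of *Lecudina longissima*, with the locality it came
from" must chase each occurrence to its archive files, search the
taxonomy table by hand, and trace matching read labels back into the
sequence file — per occurrence, sometimes thousands of times.

`occseq` automates that chain for evolutionary biologists and
biogeographers. Given a genus (`"Lecudina"`) or binomial
(`"Lecudina longissima"`) query it:

1. pages through GBIF-style occurrence-search results for the taxon;
2. resolves and downloads each occurrence's linked sequence resources
   (FASTA/FASTQ + MAPseq files, plain or gzipped) into a per-occurrence
   cache, with retry and atomic writes;
3. scans each MAPseq table for reads classified as the query taxon —
   matching is **exact on normalized lineage tokens** (rank prefixes such
   as `g__`/`s__` stripped, underscores to spaces, case-folded), with a
   genus-prefix rule so a genus query matches its species but
   `"lecudina"` never matches `"paralecudina"`;
4. extracts exactly the matching reads from the sequence files; and
5. writes a master FASTA whose headers are prefixed with the source
   occurrence id, linked row-for-row to an occurrence/locality CSV, plus
   a coverage summary: the fraction of occurrences that carried
   next-generation SSU data at all.

Everything also runs fully offline: a deterministic fixture generator
emulates the occurrence API, the archives, and the taxonomy files, with
a ground-truth manifest — so the whole pipeline is testable without a
network connection.

## Worked example (offline)

```r
library(occseq)

fx <- file.path(tempdir(), "fixture")
generate_fixture("Lecudina longissima", fx,
                 n_occurrences = 8, p_with_resources = 0.6, seed = 42)

proj <- file.path(tempdir(), "lecudina_project")
report <- run_pipeline(proj, "Lecudina longissima",
                       transport = fixture_transport(fx))
report
#> <project_report>
#>   occurrences searched:      8
#>   with NGS SSU data:        5 (62.5%)
#>   sequences extracted:       78
```

Eight occurrences were searched; five of them carried both a sequence
file and a MAPseq file (62.5% coverage), and 78 reads classified as
*Lecudina longissima* were extracted. The project directory now holds:

```
seq_master.FASTA   occurrences.csv   coverage.png   coverage.json
run.log            downloads/<occurrence_id>/...
```

`occurrences.csv` links each occurrence to its locality and its share of
the master file (absent coordinates stay empty, never zero):

```
  occurrence_id     scientific_name decimal_latitude decimal_longitude country n_sequences had_ngs_ssu
1        146208 Lecudina longissima         -53.1759          126.7555      NO           9        TRUE
2        154425 Lecudina longissima         -55.2672           17.0846      NZ          12        TRUE
3        161413 Lecudina longissima               NA                NA      BR          12        TRUE
4        174362 Lecudina longissima          85.9746          156.0788      US           0       FALSE
```

Each master-FASTA header is `<occurrence_id>_<read_label>`, so every
sequence traces back to its CSV row:

```
>146208_ERZ146208.read_0001
TAGCCTGTAACGTCCCTACCAGGAGCTCTAGAAGCCACGATCCTTTGGCGGCGGAAATAG
...
```

and `coverage.json` is the machine-readable side of the coverage plot:

```json
{"n_occurrences":8,"n_with_ngs_ssu":5,"proportion_with_data":0.625}
```

Headers can be annotated with CSV metadata afterwards
(`annotate_fasta(master, csv, c("decimal_latitude", "decimal_longitude"))`
appends `|`-joined values, e.g. `>146208_ERZ146208.read_0001|-53.1759|126.7555`).

## Command line

A thin CLI mirrors the library:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","occseq.R",package="occseq"))')" \
    /path/to/project "Lecudina longissima" \
    [--offline <fixture_dir>] [--max-occurrences N] [--page-size N] \
    [--annotate country,decimal_latitude] [--no-cache] [--log-level quiet]
```

Without `--offline` it talks to the live GBIF occurrence API. Exit
status is 0 even when zero sequences are found — an empty harvest is a
valid finding, not an error.

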