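---
title: "Harvesting occurrence-linked SSU rRNA sequences: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harvesting occurrence-linked SSU rRNA sequences: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(occseq)
```

## What the pipeline computes

For a taxon query, `occseq` assembles the set of next-generation
small-subunit (SSU) rRNA reads that biodiversity occurrence records link
to, each read bound to the occurrence (and hence the locality) it came
from. The procedure is a chain of deterministic set operations rather
than a statistical model, so the "method" is the precise contract at
each link:

1. **Query parsing.** A query is one token (genus or higher rank) or two
   tokens (a species binomial); three or more words is an error, not a
   silent truncation — the input is undefined and failing loudly beats
   guessing. Tokens are lowercased once at parse time, so all later
   matching is case-insensitive by construction.
2. **Occurrence search.** Occurrence payloads arrive in the
   occurrence-search JSON dialect (a `results` array plus an
   `endOfRecords` flag), fetched in pages of `page_size` (default 300,
   the common occurrence-API limit) with increasing offset. The returned
   record list is invariant to the page size — a property the test suite
   checks directly. A page that still fails after 3 attempts with
   exponential backoff aborts the whole search: returning partial
   results silently would corrupt the coverage denominator.
3. **Coordinate hygiene.** Coordinates are decimal degrees, WGS84
   assumed. A pair is kept only if both members are present and in range
   (|lat| ≤ 90, |lon| ≤ 180); otherwise both are dropped, because a
   half-valid locality cannot be mapped and a sentinel value would be
   worse than an honest absence.
4. **Resource resolution.** Linked resource URLs are classified by file
   suffix (case-insensitive; a trailing `.gz` marks gzip and is stripped
   first) and fetched into `downloads/<occurrence_id>/` under the
   project folder. The cache key is an MD5 digest of the URL; files are
   written to a temporary name and renamed into place, so an
   interrupted run never leaves a partial file under a final name, and
   an intact cache makes re-runs byte-identical.
5. **Taxonomy decode.** MAPseq-style assignment files are tab-delimited,
   one read per line, label in column one; the right-most tab field
   containing `;`-separated tokens is taken as the lineage. Tokens are
   normalized (rank prefix `<letters>__` stripped, underscores to
   spaces, trimmed, lowercased — an idempotent transform). A monomial
   query matches a lineage if some token equals the query or some
   token's first word does (so a genus finds its species); a binomial
   matches only a token equal to the full two-word form. Matching is
   exact on whole tokens, never substring.
6. **Extraction and aggregation.** Exactly the matching labels are
   pulled from the companion FASTA/FASTQ files (file order preserved,
   FASTQ qualities discarded since the terminal product is FASTA) and
   written to `seq_master.FASTA` with headers
   `<occurrence_id>_<read_label>`, alongside `occurrences.csv` and a
   coverage summary.

## Why exact-token matching

The matching semantics are the main correctness risk of the whole tool.
A literal free-text search over the taxonomy file would match name
fragments: a genus query `lecudina` would hit `Paralecudina` and
`Lecudinaella`, quietly inflating the harvest with the wrong organisms.
We therefore normalize lineage tokens and compare whole strings, with
one deliberate asymmetry: a genus query also accepts any token whose
first word is the genus, because species tokens of the form
`"lecudina longissima"` are genuinely members of the genus. The fixture
generator makes this rule falsifiable: every generated taxonomy file
carries adversarial near-miss decoys — superstring genera
(`<Genus>ella`, `Para<genus>`), sibling species, superstring epithets,
and (against binomial queries) genus-only lineages — and the tests
require zero decoys in every match set. Binomial matches are provably a
subset of the corresponding genus matches, and the streaming
implementation is checked for equality against a naive
parse-everything-then-filter reference on randomized files.

If strict reproduction of a substring-style search were ever needed it
could be added behind a flag; it is deliberately not the default.

## What counts as "having NGS SSU data"

The coverage summary reports the proportion of searched occurrences that
link to next-generation SSU data at all. An occurrence counts as having
data when **both** a sequence file and a MAPseq file were fetched
successfully — independent of whether any read matched the query. The
two files are jointly necessary to decode anything; an occurrence with
one but not the other contributes zero sequences, is logged with a
warning, and counts as lacking data. Conversely, an occurrence whose
files were present but contained no matching reads still counts as
having data: availability and match success are different questions, and
conflating them would make the coverage plot depend on the query rank.
The plot's numbers live in a JSON sidecar (`coverage.json`), which is
the machine-testable surface; the PNG is for humans.

## Output conventions

Master headers concatenate occurrence id and read label with `_`; a
collision (the same label extracted twice for one occurrence, e.g. from
both a FASTA and a FASTQ) appends `.2`, `.3`, … in order of appearance.
Reads with identical bases from *different* occurrences are retained —
each occurrence's evidence stands alone, and deduplicating across
localities would destroy the linkage the tool exists to provide.
Occurrences are processed in ascending id order and files in link order,
so outputs are reproducible and diffable. The CSV is RFC 4180, UTF-8,
absent values as empty fields. Header annotation joins requested CSV
columns with `|`, which is FASTA-header-safe and absent from read
labels; its presence is also how re-annotation of an already annotated
file is detected and refused, preventing silent header corruption.

## The fixture generator: what it emulates, and what not

`generate_fixture()` builds a complete offline project: paginated
occurrence payloads (with the linked-resource URLs carried in a
dedicated `associated_sequence_resources` list — the one adapter-level
choice that a live-API mapping would isolate), per-occurrence FASTA or
FASTQ files (a mix of plain and gzipped), MAPseq files in which exactly
the manifest's `matching_labels` carry the taxon's lineage, and a
ground-truth manifest, all byte-identically reproducible from a seed.

Defaults, chosen once as a realistic small survey: 8–25 matching and
6–20 decoy reads per resource-bearing occurrence; read lengths uniform
on 150–1800 nt (the span from short amplicon reads to near-full-length
SSU contigs); 10% of occurrences without coordinates; half of all
resource files gzipped; 30% of sequence files FASTQ. Bases are uniform
over ACGT: the fixtures exercise *linkage* correctness, for which
biological sequence realism is irrelevant.

What fixtures deliberately do not emulate: live-API schema drift, rate
limits, authentication, and failure modes beyond a truncated transfer
retried to success and the end-of-records signal. Passing tests
therefore demonstrate the pipeline's bookkeeping — pagination, caching,
matching, extraction, linkage, determinism — not robustness to every
behaviour of the live services, whose payload-field mapping is confined
to one thin transport adapter.

## Numerical and degenerate-input choices

There is no floating-point estimation anywhere; the only derived
quantity is the coverage proportion `n_with_data / n_occurrences`,
defined as 0 when no occurrences were searched (the plot then states
"no occurrences" rather than dividing by zero). Zero harvested
sequences is a valid result and exits successfully. Malformed MAPseq
lines are tallied and reported, never fatal — a single bad row must not
abort a file of hundreds of thousands. Malformed FASTA/FASTQ (sequence
data before the first header; a FASTQ record whose base and quality
lengths differ) is fatal with the record index named, since it
indicates a corrupted download rather than archive noise.

## Problem sizes used by the checks

The shipped verification runs at small scale, chosen so the suite stays
quick while every contract is still exercised across its boundary cases:
an end-to-end fixture of 50 occurrences at 60% resource coverage, 100+
randomized taxonomy files of up to 1000 lines for the matching oracle,
100+ randomized sequence files for the extraction oracle, and the
549-occurrence / 2-sequenced coverage configuration for the summary
computation. All scale knobs (`n_occurrences`, `reads_per_occurrence`,
`page_size`, …) are ordinary arguments, so the same harness runs at any
size.

## Known limitations

* Matching is purely lexical against the file's lineage strings; there
  is no taxonomic name resolution or fuzzy matching against a backbone,
  so a misspelled query harvests nothing (by design — the query string
  is used verbatim).
* MAPseq identity/confidence scores are not used for filtering, and no
  quality trimming, chimera checking, length filtering or clustering is
  applied to the harvested reads.
* Downloads are sequential; there is no parallel scheduler and no
  checksum verification beyond a size/emptiness check, since none is
  published for the resources.
* The live HTTP transport is a thin adapter over base R connections and
  is not exercised against the real services in the offline test suite.
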