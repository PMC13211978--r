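# brapifed

A federated proxy for the Breeding API (BrAPI v2.1), with a synthetic
mock federation and a marker–trait validation client — in R.

## The problem

Genebank and breeding projects routinely keep phenotypic and genotypic
data in separate backends: passport data and trait observations in a
relational database, genotype matrices (derived from VCF) in per-crop
variant-browser instances. Each backend can expose its own private BrAPI
endpoint, but downstream tools want *one* standards-compliant endpoint
over all of them. Merging is non-trivial in exactly three places:

1. **List pagination.** A BrAPI list response is one page of a large
   list. The federated list is the concatenation of N backend lists, so
   serving global page *p* at size *s* means locating the global item
   window `[p·s, p·s + s)` inside the per-backend lists, fetching only
   the (at most two) backend pages that overlap it per backend, and
   recomputing `totalCount`/`totalPages` globally.
2. **The allele matrix.** `/allelematrix` is paged in **two**
   dimensions (variants × callsets). The federated matrix is
   block-diagonal: a cell pairing a variant from one backend with a
   callset from another cannot exist and is filled with a configurable
   missing-genotype string (default `.`, the VCF convention). Both axis
   paginations are recomputed globally.
3. **Identifiers.** Backend-local `...DbId` values collide across
   backends. Each backend gets a configured prefix (e.g. `bar`, `whe`);
   responses are namespaced (`bar-v19`), and requests are routed back by
   longest-prefix resolution. Prefixes must be prefix-free, so
   resolution is provably unambiguous; one backend may carry the empty
   prefix and acts as the fallback for unprefixed ids.

On top of the proxy, the package re-implements the client-side
validation workflow such a federation exists for: select variants near a
marker position, walk the linkage chain
**variant → allele matrix → callset → sample → germplasm → observation**,
compare the trait distribution across genotype classes with a two-sided
Wilcoxon rank-sum test (exact by exhaustive enumeration for combined
n ≤ 20 — valid even under heavy ties — and tie-corrected normal
approximation above; Kruskal–Wallis across the three diploid classes
when all are populated; Bonferroni across the window), and tabulate the
passport attributes and study years of alternate-allele carriers.

Everything is testable offline: `generate_world()` builds a synthetic
federation (one passport/phenotype source, one genotype source per
crop) with Hardy–Weinberg genotypes at Uniform(0.1, 0.9) allele
frequencies and a planted marker–trait effect
`y = mu + beta·dosage + N(0, sigma)`.

## Worked example

```r
library(brapifed)

w    <- generate_world(seed = 42)                  # 2 crops, 100 + 40 callsets
fed  <- world_federation(w, serverTokens = "sesame")
conn <- proxy_connection(fed$proxy, token = "sesame")

res <- run_marker_validation(conn, marker_query("6H", 17007008, 5000, "Plant height"))
res
#> <marker_validation> 6H:17007008 +/- 5000 bp, trait 'Plant height'
#>   21 variant(s) in window, 20 tested
#>   top variant: bar-v19 (6H:17009885), rank-sum p = 1.02e-32 (Bonferroni 2.03e-31), n = 94 ref / 104 alt
#>   carriers: 52 germplasm; institutes: CGN Wageningen=14, ICARDA=7, INRAE URGI=3, IPK Gatersleben=15, NordGen=10, unknown=3
```

The query asks for variants within 5 kb of position 17007008 on
chromosome 6H and the trait "Plant height". The pipeline walks the
federated endpoints only: the top-ranked variant is the synthetic
world's planted variant at 6H:17009885 (served by the prefixed barley
backend, hence `bar-v19`), its rank-sum p-value compares the 94
homozygous-reference trait observations against the 104 observations of
heterozygous/homozygous-alternate carriers, and the carrier breakdown
counts germplasm per collecting institute (missing passport fields land
in `unknown`). The per-variant table is in `res$results`:

```r
head(res$results[, c("variantDbId", "position", "p_value", "n_ref", "n_alt")], 3)
#>   variantDbId position  p_value n_ref n_alt
#> 1     bar-v19 17009885 1.02e-32    94   104
#> 2     bar-v15 17007379 8.72e-02    98   100
#> 3     bar-v20 17010753 1.07e-01     6   192
```

The same proxy answers BrAPI over HTTP — `serve_federation(config)`
serves `/serverinfo`, `/commoncropnames`, the entity lists and their
`/{id}` forms, `/allelematrix`, and an OpenAPI 3 document at
`/openapi.json`:

```r
proxy_handle(fed$proxy, "GET", "/serverinfo")$body$result$calls
#> serverinfo, commoncropnames, germplasm, samples, studies, observations,
#> variants, callsets, allelematrix
```

Command-line wrappers live in `inst/scripts/` (`serve-federation.R`,
`serve-world.R`, `marker-validation.R`); a template configuration is in
`inst/extdata/example-config.yaml`.

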