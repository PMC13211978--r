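---
title: "Federating BrAPI endpoints: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Federating BrAPI endpoints: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brapifed)
```

This vignette records how the proxy merges distributed BrAPI endpoints,
what the synthetic federation emulates (and does not), and the design
choices made where more than one defensible option existed.

## The federation model

A federation is an **ordered** list of backends, each with a base URL, a
set of served endpoints, an optional bearer token, and an identifier
prefix. Order is semantic: merged lists and matrix axes are the
concatenation of the backend contributions in configuration order, with
no re-sorting. Concatenation is the only deterministic merge that
requires nothing of the backends beyond stable local ordering —
cross-backend interleaving (e.g. by genomic position) would be
meaningless across crops and would break page-window arithmetic.

### List merging

Page `p` at size `s` is the half-open global item window
`[p·s, min(p·s + s, total))` over the virtual concatenation. Serving it
requires each backend's `totalCount` for the (routed) query; these are
probed with a minimal `page = 0, pageSize = 1` request and cached for a
short TTL (30 s) keyed by endpoint and filter set, so iterating a long
result costs one probe round, not one per page. Backend fetches reuse
the caller's `pageSize`: a window of length ≤ s spans at most one local
page boundary, hence at most two local pages per backend — the proxy
never issues offset-based requests, because BrAPI only guarantees
`page`/`pageSize` semantics.

Totals are a snapshot. If a backend shrinks between probe and fetch the
slice comes up short; the proxy re-probes and replans once, and on a
second inconsistency returns a truncated page with a `WARNING` status.
This eventual-consistency contract is documented rather than solved:
the backends this proxy targets are read-mostly archives.

### The allele matrix

`/allelematrix` responses carry two pagination entries (`VARIANTS`,
`CALLSETS`). The merged matrix is block-diagonal: genotype calls exist
only where variant and callset come from the same backend, and every
cross-backend cell takes the configured `missingGenotype` fill (default
`"."`, the VCF missing-call string — no genotype backend can genotype
another backend's samples, so "missing call" is the semantically honest
value). A 2D window intersects each backend in an axis-aligned
rectangle; each axis needs at most two local pages, so a backend
contributes at most four tile fetches per federated matrix page. A
backend whose variants (but not callsets) intersect the window still
contributes variant axis labels — its rows are all fill — and vice
versa; label-only contributions are fetched with the other dimension at
size 1. Data matrices are matched across backends by `dataMatrixName`;
a name served by only some backends is still emitted, with fill over
the others' blocks (completeness over strictness).

### Identifier namespacing and routing

Rendered ids are `prefix + separator + localId` (separator default
`"-"`). Resolution matches the longest configured `prefix + separator`
head and never splits on the separator, so separators inside local ids
are harmless. Validity is enforced at configuration load: non-empty
prefixes must be pairwise distinct and prefix-free, and at most one
backend may hold the empty prefix (the fallback). Prefix-freeness makes
resolution unique; this is checked once at load time instead of being a
per-request concern.

**Ownership rule.** A `DbId` attribute is prefixed in responses (and
localized in requests) only when the backend *serves the referenced
entity's endpoint*; attribute stems that are not cross-endpoint links
(e.g. `referenceDbId`) are treated as backend-internal and always
prefixed. Identifiers of entities served elsewhere pass through in
global form, and filters on such entities are forwarded verbatim to
every capable backend. This is what keeps the linkage chain closed in
the asymmetric layout the proxy is built for: a genotype backend's
callset references a sample that lives in the relational backend, so
`sampleDbId` must keep the relational backend's (global) form — blanket
own-prefixing would make the reference unresolvable. The practical
corollary is a data contract: backends must store cross-backend
references in the federation's global form (trivially true when the
referenced backend is the unprefixed fallback, as in the intended
layout).

Unresolvable identifier filter values are dropped, not raised: BrAPI
filters are match-based, and an unknown id simply matches nothing.

### Server surface

The proxy serves `serverinfo` (open), `commoncropnames` (union of
backend crops), the entity lists with their `/{id}` single-record forms
(routed to one backend via resolution, no merging), `/allelematrix`,
and an OpenAPI 3.0 document at `/openapi.json`. All three descriptions
of the surface — live routing, `serverinfo`, OpenAPI — derive from one
function (`proxy_endpoints()`), which offers an endpoint exactly when
some backend serves it, so they cannot drift apart. Auth is a static
bearer-token allow-list (empty list = open access, the "public phase");
per-backend tokens are forwarded independently. Non-2xx mapping: 401
for auth, 404 for unknown endpoints/ids, 405 for non-GET, 502 for
backend federation failures with the backend named in the status.

The OpenAPI document is checked by an in-package structural validator
(`validate_openapi()`), covering the schema constraints the emitted
document language actually uses (version string, info block, path
templates, operation/response/parameter shape, declared path
parameters). The validator is negative-tested against deliberately
damaged documents.

### Backend client

Idempotent GETs are retried up to 3 times on network errors and HTTP
5xx with exponential backoff and multiplicative jitter; 4xx are
terminal. Every call is appended to a log
(`backend, endpoint, params, attempts, outcome`) that the tests use to
assert minimal fetching and skip-routing. Response envelopes are
validated (pagination block present and arithmetically consistent,
`data` within `pageSize`, matrix grids matching their axes) before any
merging touches them; violations map to a distinct malformed-body
error. Default timeout 30 s per backend — matrix pages from array-store
backends can be slow.

## The synthetic federation

`generate_world()` emulates the data landscape the proxy targets: one
relational passport/phenotype source (germplasm with collecting
institute and country of origin, samples, studies with years, trait
observations) and one genotype source per crop (variants with
chromosome/position, callsets, genotype matrix). Defaults: two crops
with 100 and 40 germplasm (one sample and one callset each), 30 and 20
variants placed on 6H/6A within 17.000–17.015 Mb, four studies
(2019–2022), two observations per germplasm, 2% missing calls.

Genotypes are unphased strings `0/0`, `0/1`, `1/1` drawn under
Hardy–Weinberg proportions at a per-variant alternate-allele frequency
from Uniform(0.1, 0.9). Exactly one planted variant (default at
6H:17009885) carries the trait effect: trait values are
`mu + beta·dosage + N(0, sigma)` with defaults `mu = 100`, `sigma = 10`
and `beta = 30` trait units (plant height in cm) — an effect of three
noise SDs per alternate allele. The planted variant's allele frequency
is fixed at 0.3 rather than drawn: a validation demonstration plants a
marker whose genotype classes are all observable in a panel of this
size, whereas a draw near the 0.9 edge can leave the
homozygous-reference class below any sensible minimum group size.
Missingness is applied to the *served* matrix only, after trait
simulation — phenotype does not depend on genotyping success.

What the generator deliberately does not emulate: linkage
disequilibrium between variants, multi-allelic sites, population or
pedigree structure, genotype–environment interaction, and geographic
clustering of carriers. Passing tests therefore demonstrate the
correctness of the federation mechanics and the linkage walk, and the
statistical calibration of the testing layer under independence — they
do not certify behaviour under LD-induced correlated tests or
structured panels, where rank-based association p-values are known to
need structure correction (explicitly out of scope).

## The validation pipeline

The pipeline only assumes `function(endpoint, query) -> BrAPI body`, so
it runs unchanged against the in-process proxy or any live base URL.
Variants are selected by chromosome and `|pos − target| ≤ w` with
`w = 5000` bp by default — wide enough that a confirming variant a few
kb from a literature marker falls in the window. Observations are
linked via callset → sample → germplasm; observations of germplasm
without genotype data are counted separately (not grouped), missing
cells contribute no membership, and the accounting closes per variant:
grouped + missing-excluded + ungenotyped = total trait observations
(exact when germplasm↔callset is 1:1, as generated; with multiple
callsets per germplasm the grouped counts fan out). A dangling
identifier anywhere along the chain becomes a named data-integrity
warning, not an error — surfacing isolated components is part of the
point of walking the chain.

Genotype classes come verbatim from matrix cells, with `1/0`
normalized to `0/1` (unphased semantics). The comparison is
homozygous-reference versus pooled alternate carriers, two-sided
Wilcoxon rank-sum; when all three diploid classes reach the minimum
group size (default 5 observations) a Kruskal–Wallis 3-class test is
reported alongside. Rank-based tests were chosen because trait
distributions from heterogeneous historic trials are skewed and no
normality claim is defensible. Below combined n = 20 the null
distribution is enumerated exhaustively over all group assignments
(choose(20,10) = 184,756 at worst), which stays exact under ties —
where the classical exact Wilcoxon distribution is unavailable — using
the symmetry of the midrank subset-sum distribution for the two-sided
p; above, the normal approximation with tie-corrected variance and
continuity correction is used (cross-checked against the reference
implementation in the tests). Raw p-values are reported with a
Bonferroni adjustment across the window's tested variants.

## Numerical and testing choices

Problem sizes were chosen to exercise every boundary while keeping the
default suite fast: pagination properties iterate page sizes 1–25 over
0–200 records per backend and 1–4 backends; matrix tilings use 1–10 ×
1–10 blocks with tile sizes 1–6; the end-to-end recovery study uses the
default world (140 callsets, 21-variant window) over 100 seeded
replicates at `beta = 3·sigma` and 500 replicates at `beta = 0`, whose
planted-variant p-values are checked against Uniform(0,1) by
Kolmogorov–Smirnov at α = 0.01. Degenerate inputs covered explicitly:
empty backends, zero-row/zero-column matrix blocks, windows beyond the
data, filters matching nothing, all-tied samples, and identifier
separators inside local ids.

## Known limitations

* Backends serving overlapping semantic content are treated as disjoint
  shards; no cross-backend deduplication is attempted.
* Only GET endpoints are federated; BrAPI search-POST and write
  endpoints are out of scope, as are rate limiting and user management.
* The HTTP front end is single-threaded by design (one connection at a
  time); concurrency belongs to a reverse proxy in front of it.
* The probe cache makes totals eventually consistent under concurrent
  backend mutation; see the truncation contract above.
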