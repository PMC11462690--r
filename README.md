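# methylogo

Methylation-aware sequence logos for transcription factor binding sites.

Some transcription factors (MYC, SP1, ZBTB33, ...) bind CpG-containing
motifs whose cytosines can be methylated, and whole-genome bisulfite
sequencing (WGBS) measures that methylation per cytosine. A classical
sequence logo shows only base preferences; `methylogo` extends it so that a
single figure also shows, against a background model appropriate to the
genome region, (i) how methylated the binding-site cytosines are, and
(ii) how much information the motif gains from dinucleotides — typically
the strongly depleted CpG — that a zero-order background cannot represent.

## The model

All column heights are Kullback–Leibler relative entropies in bits,
`D(M‖B) = E[ lg P(s|M) / P(s|B) ]`, between the motif model `M` (a PWM:
independent per-position base probabilities estimated from `n` aligned
sites) and a background model `B` estimated from the whole genome (WG) or
from promoter regions (PR, TSS −1000..+200 bp). Three tracks decompose this
information:

* **Sequence track** — against a zero-order (independent-base) background
  `q`: column `i` has height `Σ_b p_i(b) lg(p_i(b)/q(b))`; letters within a
  column are scaled by their probability.
* **Dimer track** — the *extra* information of a first-order (dimer)
  background over the zero-order one, `D(M‖B₁) − D(M‖B₀)`, which decomposes
  exactly into one bar per adjacent pair,
  `Σ_{a,b} p_{j,j+1}(a,b) lg( q(a)q(b) / q(a,b) )`,
  when `q` is the marginal of the dimer joint `q(a,b)`. Positive bars mark
  under-represented dimers (CpG); dashed lines show the theoretical extrema
  of the per-pair log-ratio.
* **Methylation track** — cytosine methylation propensity depends on the
  trinucleotide context (CG, CHG, CHH, strand-relative), so each column
  decomposes over the 6 strand × context classes:
  `P(ctx,s|i) · KL2( m_{i,ctx,s} ‖ m_bg(ctx) )`,
  where `KL2` is the binary relative entropy between the observed and
  background methylation probability. Reverse-strand components are drawn
  downward.

In the logo itself, C and G glyphs are partially shaded to their observed
methylation level (forward / reverse strand respectively), with a dashed
segment at the level expected under the background given the site's
contexts; a key box lists the background base and methylation
probabilities. A companion display (`methylscape()`) profiles context
probability, methylation and methylation relative entropy across a window
flanking the motif.

## Worked example

Everything runs on simulated data with known ground truth — no downloads.
Here we plant 200 hypo-methylated `CACGTG` (E-box) sites into a 100 kb
CpG-depleted genome whose background CpGs are 80% methylated:

```r
library(methylogo)

sim <- simulate_dataset(tempfile("demo"), genome_length = 100000L,
  consensus = "CACGTG", n_sites = 200L, site_cg_level = 0.05, seed = 42L)
mt  <- merge_replicates(sim$replicates)   # depth > 4 per replicate, mean level
fit <- methylogo(sim$sites, sim$genome, mt)
fit
#> Methylation-aware sequence logo model
#>
#>   sites:      200 aligned binding sites, L = 6, flank = 10 bp
#>   background: WG
#>   consensus:  CACGTG
#>
#>   sequence track    11.757 bits
#>   dimer track        1.099 bits
#>   methyl track       2.950 bits
#>   total             15.806 bits

plot(fit, file = "logo.svg")              # or .pdf / .png
write_tracks(fit$tracks, "tracks.tsv")    # numeric values behind the figure
```

The summary shows where the information sits — nearly all methylation
information at the planted CpG (motif positions 2/3, observed ~0.05 vs an
expected ~0.72), and the tallest dimer bar (1.54 bits) at the CpG step:

```r
summary(fit)
#>  pos consensus seq_bits meth_bits obs_meth_fwd exp_meth_fwd
#>    2         C     2.02  1.49e+00       0.0468       0.7174
#>    3         G     2.02  1.46e+00           NA           NA  ...
#> Dimer bars (bits): -0.267 0.048 1.538 0.048 -0.267
```

The flanking profile and a promoter-region background work the same way:

```r
sc <- methylscape(sim$sites, sim$genome, mt, window = 10L)
plot(sc, file = "scape.svg")

tss <- read_tss(sim$tss)
pr  <- promoter_regions(tss, sizes = chrom_sizes(sim$genome))
fit_pr <- methylogo(sim$sites, sim$genome, mt, regions = pr)   # label "PR"
```

A thin command-line wrapper is installed under `exec/methylogo` with
subcommands `background`, `logo`, `scape` and `simulate`; backgrounds can
be precomputed once (`background` writes a JSON bundle) and reused.

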