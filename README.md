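# clonedd

Clonal division-destiny analysis for lymphocyte family trees.

When activated T cells proliferate, each lineage stops dividing at a
characteristic generation — its *division destiny* (DD).  Multiplex
division-tracking flow cytometry follows many clonal families (the progeny
of single founder cells) at once, but recovers only a fraction of each
family's cells.  `clonedd` is for immunologists and modellers who want to
ask, from such clone tables:

* **How concordant is DD within a family?**  A beta-binomial correlated
  family-tree model: of the $c_k$ cells in generation $k$, a beta-binomial
  $(c_k, p_k, \rho)$ number progresses, the rest become quiescent, and the
  realized tree is observed through independent binomial sampling with
  probability $r$.  The package enumerates all full trees, computes exact
  tree and sampled-subtree likelihoods, predicts the distribution of the
  clonal *range* (max − min observed generation), and fits the
  within-family correlation $\rho \in [0,1]$ by maximum likelihood.
* **Do costimulatory signals add independently at clone level?**  A
  tree-concatenation algebra in which the quiescent-cell generation counts
  of a summed family tree are the convolution of the inputs, making mean DD
  (mDD, cohort-normalized) and maximum DD (maxDD) linear statistics; the
  maximum-likelihood estimator of the CDF of a sum as the convolution of
  empirical CDFs with percentile-bootstrap bands; and a dedicated
  $\chi^2$ test, $S = V'\Sigma^{+}V$ with
  $V = \sqrt{n_X}(\hat x * \hat y - \hat a * \hat b)$ and $\Sigma$ the
  delta-method covariance, for equality of two convolved categorical
  distributions.
* **What do clone-level fates imply in vivo?**  Contribution curves
  re-introducing expansion ($N_i = f_i\, mN_0\, 2^i$) and DD inference from
  clone sizes ($\mathrm{DD} = \lceil \log_2 N \rceil$).

Because the assay's clone-level data are not deposited anywhere, a
synthetic-data module generates clone tables with the full observation
model (harvest-time truncation, binomial recovery, quiescence
misclassification) and serves as the ground-truth bed for every test.

## Worked example

Simulate the default four-condition study (founder inputs 96/224/96/224,
within-family correlation 0.9, recovery 0.9, 4% quiescence
misclassification), summarize clones, and fit the correlation for one
condition:

```r
library(clonedd)

tab  <- simulate_clone_table(seed = 1)
summ <- clone_summary(tab)
head(summ, 4)
#>   clone_id condition n_detected range         class ordered mdd maxdd
#> 1 N4_c0001        N4          7     0 all-quiescent      NA   3     3
#> 2 N4_c0002        N4         14     0         mixed    TRUE  NA    NA
#> 3 N4_c0003        N4         28     1         mixed   FALSE  NA    NA
#> 4 N4_c0004        N4          5     0 all-quiescent      NA   3     3
mean(summ$range == 0)   # fraction of concordant clones
#> [1] 0.859
```

86% of simulated clones are perfectly concordant (range 0).  Fit the
within-family correlation from the fully quiescent N4 clones and compare
the predicted range distribution with a finite-sample envelope:

```r
dd   <- filter_dd_clones(tab)
sub  <- dd[dd$condition == "N4", ]
gens <- rep(sub$generation, sub$n_cells)
ids  <- rep(sub$clone_id, sub$n_cells)
D    <- max(gens)
prof <- estimate_progression(tabulate(gens + 1, D + 1), max_depth = D)
S    <- t(vapply(split(gens, ids),
                 function(g) tabulate(g + 1, D + 1), integer(D + 1)))

fit <- fit_rho(S, prof, r = 0.9)
fit
#> Within-family DD correlation fit
#>   rho MLE: 0.8612  (log-likelihood -194.512)

range_distribution_ci(range_distribution(dd_model(prof, fit$rho, 0.9)),
                      n_families = nrow(S))
#>   range    prob  lower upper
#> 1     0 0.76625 0.6481 0.870
#> 2     1 0.16869 0.0741 0.278
#> 3     2 0.05641 0.0000 0.130
#> ...
```

The fitted $\rho$ of 0.86 recovers the generator's strong family
correlation of 0.9: even with every cell observed in only ~90% of wells,
this level of correlation is needed to reproduce so many range-0 clones.
The `prob` column is the model's predicted share of recovered families at
each range; `lower`/`upper` bracket what an experiment recovering
`n_families` clones would show.

A command-line interface wraps the same pipeline
(`Rscript inst/cli/clonedd.R simulate|summarize|fit-concordance|test-addition|invivo ...`);
all randomized commands take `--seed` and are bit-reproducible.

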