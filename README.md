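# loopnoise

Stochastic gene expression driven by two interacting chromatin loops.

Enhancers often reach their promoter through a DNA loop, and insulator
pairs (such as Su(Hw) sites) form a second loop that can assist, ignore,
or interfere with the first depending on how the two loops are arranged
along the chromosome.  `loopnoise` is for quantitative/systems biologists
who want to ask how that loop–loop interaction shapes the *distribution*
of mRNA copy numbers in single cells — mean expression, noise intensity
(squared coefficient of variation), skewness, kurtosis — rather than just
the average.

## The model

A gene with a blue enhancer–promoter loop (length `d1`) and a green
insulator-pair loop (length `d2`) is mapped to a four-state promoter
(OFF1, OFF2, ON1, ON2 = neither / green / blue / both loops formed) with
transitions along the square cycle.  Transcription runs at rate μ in the
two blue-looped states; mRNA degrades at rate δ.  Looping rates follow an
empirical length law

    k_loop(d) = exp(−u/d − v·ln d + w·d + z),    u = 140.6, v = 2.52,
                                                 w = 0.0014, z = 19.9,

the partner loop rescales them by a pattern factor k (nested:
4·exp(−d/2)+1; side-by-side: 1; alternating: 0.5), and facilitated
tracking adds Δ = r·d with tracking ratio r (r = 0 is direct looping).

The resulting chemical master equation is solved *exactly* by the
binomial-moment method: the per-state moments b_k = Σ_m C(m,k)·P_i(m)
obey the closed triangular recursion

    (kδ·I − A)·b_k = Λ·b_{k−1},

and the stationary distribution is recovered from the totals B_k through
P(m) = Σ_{k≥m} (−1)^{k−m}·C(k,m)·B_k, with mean B_1 and noise
η = (2B_2 + B_1 − B_1²)/B_1².  The alternating sum is evaluated in
compensated double-double arithmetic (the cancellation kills plain
doubles), and two independent oracles — direct finite state projection
and an exact Gillespie simulator — cross-check every distribution.
Closed-form hypergeometric laws (₁F₁ telegraph-like, ₂F₂ and ₃F₃-mixture
families) are provided for the special cases that admit them.

## Worked example

Mean, noise and full copy-number distribution for a nested pair of loops
(blue loop 50, green loop 1500, transcription 10, degradation 1), checked
against the projection and simulation oracles:

```r
library(loopnoise)

cfg <- loop_config("nested", d1 = 50, d2 = 1500,
                   k1 = "preset", k1_dist = "d1", k2 = 0.5)
gp  <- config_generator(cfg)
mom <- solve_moments(gp$A, gp$Lambda)
summary_stats(mom)
#> <summary_stats> mean=9.99797 var=9.99799 eta=0.10002 fano=1
#>   skewness=0.31626 kurtosis=3.10002

pmf <- reconstruct_distribution(mom)
pmf
#> <mrna_pmf> method=reconstruction support=0..58 mean=9.9980 var=9.9980

sup_dist(pmf, fsp_steady_state(gp$A, gp$Lambda))
#> [1] 5.551115e-16

sim <- ssa_simulate(build_rate_set(cfg), 10, 10, 1,
                    sim_plan(40, 8, n_cells = 2000, seed = 1),
                    record = FALSE)
h <- stationary_histogram(sim)
c(mean = attr(h, "mean"), se = attr(h, "mean_se"))
#>        mean          se
#> 9.995129822 0.016767872
```

At these lengths both loops form much faster than they dissolve, so the
promoter is almost always active: the mean sits just under μ = 10 and the
noise just above the Poisson floor 1/μ.  Shorter blue loops (d1 ≲ 30)
enter the regime where looping is rate-limiting and the pattern factors
separate the three loop arrangements: `sweep_blue_length()` tabulates
mean and η across patterns and lengths, and
`relative_change_curve()` quantifies how facilitated tracking (r > 0)
shifts them relative to direct looping.

A thin command-line front end wraps the same functions:

```sh
Rscript inst/cli/loopnoise solve --pattern nested --d1 300
Rscript inst/cli/loopnoise simulate --pattern alternating --d1 300 \
        --k1 0.5 --k2 0.5 --n-cells 100 --seed 1
Rscript inst/cli/loopnoise sweep --preset fig3 --out sweep.tsv
Rscript inst/cli/loopnoise validate
```

`validate` prints the oracle-triangle report (reconstruction vs FSP
sup-norm, simulation z-scores) and the tracking-comparison maxima under
both readings of the tracking modification.

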