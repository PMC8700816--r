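# Small designs and term sets shared across tests.

fx <- nanoemulsion_runs()

# 7-run simplex-centroid-ish design with no replicates
simplex7 <- mixture_design(rbind(
  c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
  c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5),
  c(1, 1, 1) / 3))

terms_q <- scheffe_terms(3, "quadratic")
terms_rc <- scheffe_terms(3, "reduced-cubic")

# explicit residual sum of squares from a bare least-squares refit
rss_of <- function(design, z, terms) {
  X <- model_matrix(design, terms)
  sum(stats::lm.fit(X, z)$residuals^2)
}
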