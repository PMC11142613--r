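# Shared fixtures built in code.

# Independent closed-form oracle for the composed transform: coded directly
# from the piecewise definition, not via mirror/contract.
fcu_oracle <- function(x) ifelse(x >= 1, x - 1, 1 - 1 / x)

# Log-spaced probe grid over [2^-10, 2^10].
fc_grid <- function(n = 1e4) 2^seq(-10, 10, length.out = n)

toy_results <- function() {
  tibble::tibble(
    feature_id = c("a", "b", "c"),
    fc = c(4, 1/4, 1),
    pvalue = c(1e-4, 1e-3, 0.5),
    padj = c(1e-3, 5e-3, 0.8),
    base_mean = c(100, 50, 0)
  )
}
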