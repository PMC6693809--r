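# shared tiny builders for tests

# a small complete dataset with one of each variable type
toy_dataset <- function(n = 40, seed = 99) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    vals <- data.frame(
      y = rnorm(n),
      x = rnorm(n),
      b = rbinom(n, 1, 0.5),
      g = factor(sample(c("lo", "mid", "hi"), n, TRUE),
                 levels = c("lo", "mid", "hi")))
    miss_dataset(vals, roles = c(y = "outcome", x = "exposure",
                                 b = "confounder", g = "confounder"))
  })
}

# expand a 2x2 table (exposed-case layout) into unit records
records_2x2 <- function(a, b, c, d) {
  data.frame(
    x = c(rep(1, a + b), rep(0, c + d)),
    y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)))
}
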