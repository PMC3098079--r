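test_that("sentence length statistics use the midpoint median rule", {
  s <- sentence_length_stats(c(1, 2, 3))
  expect_equal(s$median, 2)
  expect_equal(s$mean, 2)
  s2 <- sentence_length_stats(c(2, 4))
  expect_equal(s2$median, 3)
  expect_equal(s2$mean, 3)
  # from sentence strings
  s3 <- sentence_length_stats(c("one two three", "four five"))
  expect_equal(s3$lengths, c(3, 2))
  expect_error(sentence_length_stats(numeric(0)))
})

test_that("length statistics match a sort-based oracle on random samples", {
  set.seed(17)
  for (rep in 1:10) {
    x <- sample.int(60, sample(3:40, 1), replace = TRUE)
    s <- sentence_length_stats(x)
    srt <- sort(x); n <- length(srt)
    med <- if (n %% 2 == 1) srt[(n + 1) / 2] else
      (srt[n / 2] + srt[n / 2 + 1]) / 2
    expect_equal(s$median, med)
    expect_equal(s$mean, sum(x) / n)
  }
})

test_that("lognormal sentence lengths have the closed-form mean", {
  # closed-form lognormal mean exp(mu + sigma^2/2) as the oracle
  mu <- 3.2; sigma <- 0.35; n <- 5000
  set.seed(12)
  x <- rlnorm(n, mu, sigma)
  s <- sentence_length_stats(x)
  true_mean <- exp(mu + sigma^2 / 2)
  se <- sqrt((exp(sigma^2) - 1) * exp(2 * mu + sigma^2)) / sqrt(n)
  expect_lt(abs(s$mean - true_mean), 3 * se)
})

test_that("function-word percentage is an exact ratio", {
  expect_equal(function_word_percentage(
    c("the", "cat", "sat", "on", "the", "mat"), c("the", "on")), 50)
  expect_equal(function_word_percentage(c("the", "of"), c("the", "of")),
               100)
  expect_equal(function_word_percentage(c("cat", "mat"), c("the")), 0)
  expect_error(function_word_percentage(character(0)))
})

test_that("syntactic complexity index applies the 2/2/1/1 weights", {
  tag <- function(classes) data.frame(token = paste0("w", seq_along(classes)),
                                      class = classes,
                                      stringsAsFactors = FALSE)
  expect_equal(syntactic_complexity_index(tag(rep("other", 5))), 0)
  expect_equal(syntactic_complexity_index(
    tag(c("subordinator", "verb", "verb", "noun"))), 2 + 2 + 1)
  expect_equal(syntactic_complexity_index(
    tag(c("wh", "subordinator", "noun", "noun", "verb"))),
    2 + 2 + 1 + 1 + 1)
  expect_error(syntactic_complexity_index(list(1, 2)), "unlabeled")
})

test_that("index reproduces independent hand tallies on a labeled fixture", {
  # ten hand-labeled sentences; expected = 2*sub + 2*wh + verbs + nouns,
  # tallied by hand from the class strings below
  fixtures <- list(
    list(c("noun", "verb", "other"), 2),
    list(c("subordinator", "noun", "verb", "noun"), 5),
    list(c("wh", "verb", "noun"), 4),
    list(c("other", "other"), 0),
    list(c("noun", "noun", "noun"), 3),
    list(c("subordinator", "wh", "verb"), 5),
    list(c("verb", "verb", "verb", "other"), 3),
    list(c("subordinator", "subordinator", "noun"), 5),
    list(c("wh", "wh", "other", "verb", "noun"), 6),
    list(c("noun", "verb", "subordinator", "wh", "other"), 6))
  for (fx in fixtures) {
    tt <- data.frame(token = paste0("w", seq_along(fx[[1]])),
                     class = fx[[1]], stringsAsFactors = FALSE)
    expect_equal(syntactic_complexity_index(tt), fx[[2]])
  }
})

test_that("index is additive over concatenated labeled sentences", {
  a <- data.frame(token = c("because", "mice", "ran"),
                  class = c("subordinator", "noun", "verb"))
  b <- data.frame(token = c("which", "grew"), class = c("wh", "verb"))
  expect_equal(syntactic_complexity_index(rbind(a, b)),
               syntactic_complexity_index(a) +
                 syntactic_complexity_index(b))
})

test_that("binning produces a proper distribution", {
  d <- bin_distribution(c(1, 2, 3, 4, 5), bins = 4)
  expect_equal(sum(d$prob), 1, tolerance = 1e-9)
  expect_true(all(d$prob >= 0))
  expect_length(d$edges, 5)
  # shared-edge binning of two samples
  e <- seq(0, 10, length.out = 6)
  p <- bin_distribution(c(1, 2, 3), edges = e)
  q <- bin_distribution(c(7, 8, 9), edges = e)
  expect_equal(p$edges, q$edges)
})

test_that("KL divergence: identity, closed form, and error cases", {
  p <- structure(list(prob = c(1, 0), edges = c(0, 1, 2), metric = "m"),
                 class = "score_distribution")
  q <- structure(list(prob = c(0.5, 0.5), edges = c(0, 1, 2),
                      metric = "m"),
                 class = "score_distribution")
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(p, q), log(2))
  expect_equal(kl_divergence(p, q, base = 2), 1)
  r <- structure(list(prob = c(1, 0), edges = c(0, 5, 9), metric = "m"),
                 class = "score_distribution")
  expect_error(kl_divergence(p, r), "mismatched")
})

test_that("KL(p,p) = 0 and KL >= 0 over randomized distributions", {
  set.seed(23)
  for (rep in 1:50) {
    k <- sample(3:12, 1)
    pr <- rgamma(k, 1); pr <- pr / sum(pr)
    qr <- rgamma(k, 1); qr <- qr / sum(qr)
    e <- seq(0, 1, length.out = k + 1)
    p <- structure(list(prob = pr, edges = e, metric = "m"),
                   class = "score_distribution")
    q <- structure(list(prob = qr, edges = e, metric = "m"),
                   class = "score_distribution")
    expect_equal(kl_divergence(p, p), 0)
    expect_gte(kl_divergence(p, q), 0)
  }
})

test_that("KL between planted lognormal length distributions grows with the mean gap", {
  # numerical-integration oracle: KL between the two binned lognormals is
  # positive and increases with |delta mu|
  set.seed(41)
  base <- rlnorm(20000, 3.2, 0.35)
  kl_at <- function(dmu) {
    other <- rlnorm(20000, 3.2 + dmu, 0.35)
    e <- seq(min(base, other), max(base, other), length.out = 21)
    kl_divergence(bin_distribution(base, edges = e),
                  bin_distribution(other, edges = e))
  }
  k1 <- kl_at(0.1); k2 <- kl_at(0.3); k3 <- kl_at(0.6)
  expect_gt(k1, 0)
  expect_gt(k2, k1)
  expect_gt(k3, k2)
})

test_that("coarse lexical labeling feeds the index deterministically", {
  toks <- tokenize_whitespace("because the mice regulated growth which ran")
  lab <- label_lexical_classes(toks)
  expect_equal(lab$class[1], "subordinator")
  expect_equal(lab$class[lab$token == "which"], "wh")
  expect_equal(lab$class[lab$token == "regulated"], "verb")
  expect_equal(lab$class[lab$token == "mice"], "noun")
  expect_true(attr(lab, "noun_proxy"))
  expect_identical(label_lexical_classes(toks), lab)
})
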