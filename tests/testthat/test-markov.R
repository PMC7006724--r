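test_that("transition fitting matches hand counts on toy samples", {
  m <- fit_transition_model(c("AA", "AC"), pseudocount = 0)
  expect_equal(dim(m$P), c(4, 4, 1))
  expect_equal(m$P["A", "A", 1], 0.5)
  expect_equal(m$P["A", "C", 1], 0.5)
  expect_equal(m$P["A", "G", 1], 0)
  expect_equal(m$P["A", "T", 1], 0)

  # 3 sequences, 2 pairs, hand-counted
  m2 <- fit_transition_model(c("ACG", "ACT", "AGT"), pseudocount = 0)
  expect_equal(unname(m2$P["A", , 1]), c(0, 2 / 3, 1 / 3, 0))
  expect_equal(unname(m2$P["C", , 2]), c(0, 0, 1 / 2, 1 / 2))
  expect_equal(unname(m2$P["G", , 2]), c(0, 0, 0, 1))
})

test_that("pseudocount smooths unseen states to uniform rows", {
  m <- fit_transition_model(c("AA", "AA"), pseudocount = 1)
  # no sequence has C at position 1
  expect_equal(unname(m$P["C", , 1]), rep(0.25, 4))
  expect_equal(m$P["A", "A", 1], 3 / 6)  # (2+1)/(2+4)
})

test_that("every fitted transition row is a probability distribution", {
  set.seed(31)
  for (alpha in c(0, 0.5, 1)) {
    seqs <- replicate(30, random_dna(15))
    m <- fit_transition_model(seqs, pseudocount = alpha)
    expect_equal(apply(m$P, c(1, 3), sum),
                 matrix(1, 4, dim(m$P)[3]), ignore_attr = TRUE,
                 tolerance = 1e-12)
    expect_true(all(m$P >= 0 & m$P <= 1))
    if (alpha > 0) expect_true(all(m$P > 0))
  }
})

test_that("fitting is invariant to training-sequence order", {
  set.seed(32)
  seqs <- replicate(20, random_dna(10))
  m1 <- fit_transition_model(seqs, 1)
  m2 <- fit_transition_model(rev(seqs), 1)
  expect_identical(m1$P, m2$P)
})

test_that("fit errors: empty input, negative pseudocount, ragged lengths", {
  expect_error(fit_transition_model(character(0)), "empty")
  expect_error(fit_transition_model("ACGT", pseudocount = -1), ">= 0")
  expect_error(fit_transition_model(c("AC", "ACG")), "uniform")
})

test_that("markov features are per-pair (log-ratio) transition lookups", {
  set.seed(33)
  pos <- fit_transition_model(replicate(20, random_dna(41)), 1, "positive")
  neg <- fit_transition_model(replicate(20, random_dna(41)), 1, "negative")
  s <- random_dna(41)
  f <- markov_features(s, pos, neg)
  expect_length(f, 40)

  # identical class models give the all-zero vector
  expect_equal(markov_features(s, pos, pos), rep(0, 40))

  # hand lookup on a 3-mer toy
  tp <- fit_transition_model(c("ACG", "ACT"), 1, "positive")
  tn <- fit_transition_model(c("AAG", "CCT"), 1, "negative")
  f3 <- markov_features("ACG", tp, tn)
  expect_equal(f3[1], log(tp$P["A", "C", 1] / tn$P["A", "C", 1]))
  expect_equal(f3[2], log(tp$P["C", "G", 2] / tn$P["C", "G", 2]))

  # positive_prob mode lies in (0, 1] and ignores the negative model
  fp <- markov_features(s, pos, mode = "positive_prob")
  expect_true(all(fp > 0 & fp <= 1))

  expect_error(markov_features(random_dna(20), pos, neg), "length")
})

test_that("mm_score is the summed log-likelihood ratio with sign-based calls", {
  set.seed(34)
  pos <- fit_transition_model(replicate(15, random_dna(11)), 1, "positive")
  neg <- fit_transition_model(replicate(15, random_dna(11)), 1, "negative")
  s <- random_dna(11)
  expect_equal(mm_score(s, pos, neg),
               sum(markov_features(s, pos, neg, "log_ratio")))
  expect_equal(mm_score(s, pos, pos), 0)

  # sign agrees with the raw product-of-probabilities ratio on short
  # sequences where the products are computed directly
  for (i in 1:50) {
    s <- random_dna(11)
    idx <- match(strsplit(s, "")[[1]], BASES)
    prod_pos <- prod(pos$P[cbind(idx[-11], idx[-1], 1:10)])
    prod_neg <- prod(neg$P[cbind(idx[-11], idx[-1], 1:10)])
    expect_equal(sign(mm_score(s, pos, neg)),
                 sign(prod_pos / prod_neg - 1), tolerance = 1e-9)
  }
})

test_that("zero transition probabilities are a loud error in ratio mode", {
  pos <- fit_transition_model(c("AA", "AA"), pseudocount = 0)
  neg <- fit_transition_model(c("CC", "CC"), pseudocount = 0)
  expect_error(mm_score("AC", pos, neg), "pseudocount")
})

test_that("class-separated chains give positive mean training score", {
  # planted transition bias well above the noise floor
  gen <- generate_dataset(generator_config(100, 100, window_length = 21,
                                           effect_size = 0.8, seed = 35))
  seqs <- gen$set$samples$sequence
  lab <- gen$set$samples$label
  pos <- fit_transition_model(seqs[lab == "positive"], 1, "positive")
  neg <- fit_transition_model(seqs[lab == "negative"], 1, "negative")
  pos_scores <- vapply(seqs[lab == "positive"], mm_score, numeric(1),
                       pos_model = pos, neg_model = neg)
  neg_scores <- vapply(seqs[lab == "negative"], mm_score, numeric(1),
                       pos_model = pos, neg_model = neg)
  expect_gt(mean(pos_scores), 0)
  expect_lt(mean(neg_scores), 0)
})

test_that("in-fold fitting is honest: full-data models inflate accuracy", {
  # weak signal, small n: fitting the chains on all data before scoring
  # the held-out folds leaks and must look better than proper CV
  gen <- generate_dataset(generator_config(50, 50, window_length = 21,
                                           effect_size = 0.15, seed = 36))
  set <- gen$set
  proper <- cross_validate_mm(set, k = 5, seed = 1)$Acc
  seqs <- set$samples$sequence; lab <- set$samples$label
  pos <- fit_transition_model(seqs[lab == "positive"], 1)
  neg <- fit_transition_model(seqs[lab == "negative"], 1)
  leaky_scores <- vapply(seqs, mm_score, numeric(1),
                         pos_model = pos, neg_model = neg)
  leaky <- mean((leaky_scores > 0) == (lab == "positive"))
  expect_gt(leaky, proper)
})
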