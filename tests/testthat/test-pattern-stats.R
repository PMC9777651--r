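make_decoding <- function(df, K) {
  attr(df, "K") <- as.integer(K)
  df
}

test_that("O/E ratio and overrepresentation use a strict threshold of 2", {
  r <- oe_ratio(50, 25)
  expect_equal(as.numeric(r), 2)
  expect_false(attr(r, "overrepresented"))
  r2 <- oe_ratio(50.1, 25)
  expect_true(attr(r2, "overrepresented"))
  expect_equal(as.numeric(oe_ratio(13.7, 13.7)), 1)
  expect_true(is.na(oe_ratio(10, 0)))
})

test_that("exclusivity is the cluster share of all carriers, flagged at 30%", {
  expect_equal(as.numeric(exclusivity(0, 100)), 0)
  expect_equal(as.numeric(exclusivity(77, 77)), 100)
  e <- exclusivity(30, 100)
  expect_true(attr(e, "exclusive"))
  expect_false(attr(exclusivity(29, 100), "exclusive"))
  expect_true(is.na(exclusivity(0, 0)))
  expect_error(exclusivity(5, 4), "exceed")
  ## counts reconstructed from a large published-style table row
  expect_equal(as.numeric(exclusivity(4376, 6467)), 67.67, tolerance = 1e-3)
})

test_that("pattern prevalence counts members with the group", {
  feats <- data.frame(person_id = 1:5, wave = 1, g1 = c(1, 1, 0, 0, 0))
  attr(feats, "groups") <- "g1"
  dec <- make_decoding(data.frame(person_id = 1:5, wave = 1,
                                  state = c(1, 1, 1, 1, 1)), 2)
  expect_equal(pattern_prevalence(feats, dec, 1, "g1", 1), 40)
  expect_true(is.na(pattern_prevalence(feats, dec, 2, "g1", 1)))
  feats$g1 <- 1
  expect_equal(pattern_prevalence(feats, dec, 1, "g1", 1), 100)
})

test_that("statistic identities hold on group tables", {
  gen <- tiny_cohort(400, K = 3, seed = 51, n_waves = 4)
  ft <- build_feature_table(gen$panel)
  dec <- make_decoding(data.frame(person_id = gen$truth$person_id,
                                  wave = gen$truth$wave,
                                  state = gen$truth$true_state), 3)
  gs <- group_stats(ft, dec, t = 2)
  ok <- !is.na(gs$oe)
  ## oe * population prevalence = cluster prevalence, exactly
  expect_lt(max(abs(gs$oe[ok] * gs$population_prevalence[ok] -
                    gs$prevalence[ok])), 1e-10)
  ## exclusivities partition carriers: sum over patterns = 100 per group
  agg <- tapply(gs$exclusivity, gs$group, sum, na.rm = TRUE)
  carriers <- tapply(gs$population_prevalence > 0, gs$group, any)
  expect_lt(max(abs(agg[carriers] - 100)), 0.1)
  ## size-weighted cluster prevalences reproduce the population prevalence
  for (g in sample(unique(gs$group), 4)) {
    sub <- gs[gs$group == g & !is.na(gs$prevalence), ]
    wm <- sum(sub$prevalence * sub$n_pattern) / sum(sub$n_pattern)
    expect_equal(wm, sub$population_prevalence[1], tolerance = 1e-10)
  }
})

test_that("planted overrepresented groups are exactly the flagged ones", {
  ## one dominant signature group per pattern, flat background
  cc <- example_cohort_config(1200, K = 3, n_waves = 3, seed = 61,
                              separation = 0.7, background = 0.06)
  gen <- generate_cohort(cc)
  ft <- build_feature_table(gen$panel)
  dec <- make_decoding(data.frame(person_id = gen$truth$person_id,
                                  wave = gen$truth$wave,
                                  state = gen$truth$true_state), 3)
  gs <- group_stats(ft, dec, t = 1)
  common <- mptraj:::common_group_ids()
  sig <- split(sprintf("d_%03d", common), rep_len(1:3, length(common)))
  for (k in 1:3) {
    flagged <- gs$group[gs$pattern == k & gs$overrepresented %in% TRUE]
    planted <- intersect(sig[[k]], gs$group)
    expect_setequal(flagged, planted)
  }
})

test_that("empirical transitions match hand counting with exits", {
  ## person 1 stays in 1; person 2 moves 1 -> 2; person 3 dies from 1
  dec <- make_decoding(data.frame(
    person_id = c(1, 1, 2, 2, 3, 3),
    wave = c(1, 2, 1, 2, 1, 2),
    state = c(1, 1, 1, 2, 1, 3)), 2)   # K=2 -> state 3 = death
  tr <- empirical_transitions(dec)
  expect_equal(tr$matrix[1, ], c(1 / 3, 1 / 3, 1 / 3, 0), tolerance = 1e-12)
  expect_equal(rowSums(tr$matrix), rep(1, 4), tolerance = 1e-10)
  expect_equal(tr$matrix[3, 3], 1)
  ## identity case: everyone stays put
  dec2 <- make_decoding(data.frame(person_id = rep(1:3, each = 2),
                                   wave = rep(1:2, 3),
                                   state = rep(c(1, 2, 2), each = 2)), 2)
  tr2 <- empirical_transitions(dec2)
  expect_equal(tr2$permanence, c(100, 100))
})

test_that("mortality by pattern counts wave-1 members dying by the horizon", {
  dec <- make_decoding(data.frame(
    person_id = c(1, 1, 2, 2, 3, 3, 4, 4, 5, 5),
    wave = rep(1:2, 5),
    state = c(1, 3, 1, 3, 1, 1, 1, 1, 2, 2)), 2)
  m <- mortality_by_pattern(dec)
  expect_equal(unname(m), c(50, 0))
  dec_none <- make_decoding(data.frame(person_id = 1:2, wave = 1,
                                       state = c(1, 2)), 2)
  expect_equal(unname(mortality_by_pattern(dec_none)), c(0, 0))
})

test_that("top groups order by descending O/E with id tie-break and round half-up", {
  gen <- tiny_cohort(300, K = 2, seed = 71, n_waves = 3)
  ft <- build_feature_table(gen$panel)
  dec <- make_decoding(data.frame(person_id = gen$truth$person_id,
                                  wave = gen$truth$wave,
                                  state = gen$truth$true_state), 2)
  tg <- top_groups(ft, dec, t = 1, top = 10)
  for (k in unique(tg$pattern)) {
    sub <- tg[tg$pattern == k, ]
    expect_true(all(diff(sub$oe) <= 0))
  }
  ## exact ties break by ascending group id: two identical group columns
  feats <- data.frame(person_id = 1:6, wave = 1,
                      gA = c(1, 1, 0, 0, 0, 0), gB = c(1, 1, 0, 0, 0, 0),
                      gC = c(1, 1, 1, 1, 0, 0))
  attr(feats, "groups") <- c("gA", "gB", "gC")
  dtie <- data.frame(person_id = 1:6, wave = 1, state = rep(1:2, each = 3))
  attr(dtie, "K") <- 2L
  tg2 <- top_groups(feats, dtie, t = 1, top = 3)
  s1 <- tg2[tg2$pattern == 1, ]
  expect_equal(s1$group[s1$oe == s1$oe[match("gA", s1$group)]][1:2],
               c("gA", "gB"))
  expect_equal(round_half_up(2.005, 2), 2.01)
  expect_equal(round_half_up(-2.005, 2), -2.01)
})

test_that("pattern sizes partition the active population at each wave", {
  gen <- tiny_cohort(250, K = 3, seed = 81, n_waves = 4)
  dec <- make_decoding(data.frame(person_id = gen$truth$person_id,
                                  wave = gen$truth$wave,
                                  state = gen$truth$true_state), 3)
  for (t in 1:4) {
    n_active <- sum(gen$panel$wave == t & gen$panel$status == "active")
    n_dec <- sum(dec$wave == t & dec$state <= 3)
    expect_identical(n_dec, n_active)
  }
})

test_that("sequence index export is deterministic, padded and block-sorted", {
  dec <- make_decoding(data.frame(
    person_id = c(2, 2, 1, 1, 1, 3),
    wave = c(1, 2, 1, 2, 3, 1),
    state = c(2, 3, 1, 1, 1, 1)), 2)
  si <- sequence_index_export(dec, horizon = 3)
  expect_equal(names(si), c("person_id", "initial", "s1", "s2", "s3"))
  expect_equal(si$initial, c(1, 1, 2))
  ## death padded to horizon
  expect_equal(unlist(si[si$person_id == "2", c("s1", "s2", "s3")],
                      use.names = FALSE), c(2, 3, 3))
  ## permutation invariance
  perm <- sample(nrow(dec))
  dec_p <- make_decoding(dec[perm, ], 2)
  expect_identical(sequence_index_export(dec_p, horizon = 3), si)
})

test_that("demographic summary emits one row per non-empty pattern-wave", {
  gen <- tiny_cohort(300, K = 2, seed = 91, n_waves = 3)
  dec <- make_decoding(data.frame(person_id = gen$truth$person_id,
                                  wave = gen$truth$wave,
                                  state = gen$truth$true_state), 2)
  s <- summarize_patterns(gen$panel, dec, waves = c(1, 3))
  expect_equal(s$pct_female + s$pct_male, rep(100, nrow(s)))
  expect_true(all(s$n > 0))
  base <- s[s$wave == 1, ]
  expect_equal(sum(base$n), sum(gen$panel$wave == 1))
})
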