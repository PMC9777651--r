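test_that("configuration invariants are enforced", {
  dp <- matrix(0.1, 2, 60); rx <- matrix(0.1, 2, 89)
  A <- default_transition_matrix(2)
  expect_equal(rowSums(A), rep(1, 4))
  expect_equal(A[3, 3], 1)
  bad <- A; bad[1, 1] <- bad[1, 1] + 0.1
  expect_error(cohort_config(10, K = 2, transition_matrix = bad,
                             disease_profiles = dp, drug_profiles = rx),
               "rows not summing to 1.*1")
  bad2 <- A; bad2[3, 3] <- 0.9; bad2[3, 1] <- 0.1
  expect_error(cohort_config(10, K = 2, transition_matrix = bad2,
                             disease_profiles = dp, drug_profiles = rx),
               "absorbing")
  expect_error(cohort_config(10, K = 0, disease_profiles = dp,
                             drug_profiles = rx), "K must be")
})

test_that("no-exit configuration yields a full panel and frozen chains stay put", {
  dp <- matrix(0.2, 2, 60); rx <- matrix(0.2, 2, 89)
  A <- default_transition_matrix(2, permanence = 1, death = 0, dropout = 0)
  cc <- cohort_config(50, n_waves = 4, K = 2, transition_matrix = A,
                      disease_profiles = dp, drug_profiles = rx, seed = 3)
  gen <- generate_cohort(cc)
  expect_equal(nrow(gen$panel), 50 * 4)
  expect_true(all(gen$panel$status == "active"))
  ## identity on live states: state constant per person
  per <- tapply(gen$truth$true_state, gen$truth$person_id,
                function(s) length(unique(s)))
  expect_true(all(per == 1))
})

test_that("wave-1 prevalence matches the planted Bernoulli profile", {
  dp <- matrix(0.1, 2, 60); dp[1, 5] <- 0.6
  rx <- matrix(0.2, 2, 89)
  cc <- cohort_config(2000, K = 2, disease_profiles = dp,
                      drug_profiles = rx, seed = 9)
  gen <- generate_cohort(cc)
  w1 <- gen$panel[gen$panel$wave == 1, ]
  st1 <- gen$truth$true_state[gen$truth$wave == 1]
  in1 <- st1 == 1
  n1 <- sum(in1)
  phat <- mean(w1$d_005[in1])
  expect_lt(abs(phat - 0.6), 3 * sqrt(0.6 * 0.4 / n1))
})

test_that("generated panels respect monotone disease and absorbing exits", {
  gen <- tiny_cohort(150, K = 3, seed = 5, n_waves = 5)
  expect_identical(nrow(validate_panel(gen$panel)), 0L)
  ## no record after the exit wave; truth wave 1 never an exit state
  expect_true(all(gen$truth$true_state[gen$truth$wave == 1] <= 3))
  last_state <- tapply(gen$truth$true_state, gen$truth$person_id,
                       function(s) s[length(s)])
  mid_exit <- tapply(gen$truth$true_state, gen$truth$person_id,
                     function(s) any(s[-length(s)] > 3))
  expect_false(any(mid_exit))
})

test_that("empirical transitions of the truth approach the generating matrix", {
  cc <- example_cohort_config(5000, K = 3, n_waves = 5, seed = 21)
  gen <- generate_cohort(cc)
  tr <- gen$truth
  attr(tr, "K") <- NULL
  dec <- data.frame(person_id = tr$person_id, wave = tr$wave,
                    state = tr$true_state)
  attr(dec, "K") <- 3L
  emp <- empirical_transitions(dec)
  expect_lt(max(abs(emp$matrix - cc$transition_matrix)), 0.03)
})

test_that("mortality at the horizon matches the chain's absorption probability", {
  cc <- example_cohort_config(4000, K = 2, n_waves = 5, seed = 13)
  gen <- generate_cohort(cc)
  ## matrix-power absorption: start in pi over live, 4 steps
  p0 <- c(cc$initial_distribution, 0, 0)
  p4 <- p0
  for (i in 1:4) p4 <- p4 %*% cc$transition_matrix
  expected <- p4[3]
  died <- tapply(gen$truth$true_state, gen$truth$person_id,
                 function(s) any(s == 3))
  phat <- mean(died)
  se <- sqrt(expected * (1 - expected) / 4000)
  expect_lt(abs(phat - expected), 3 * se)
})

test_that("identical seed and config reproduce identical output, invariant to n", {
  cc1 <- example_cohort_config(30, K = 2, seed = 17)
  cc2 <- example_cohort_config(60, K = 2, seed = 17)
  g1 <- generate_cohort(cc1)
  g2 <- generate_cohort(cc2)
  expect_identical(g1$panel,
                   g2$panel[g2$panel$person_id <= 30, , drop = FALSE])
  g1b <- generate_cohort(cc1)
  expect_identical(g1$panel, g1b$panel)
})

test_that("panel round-trips through CSV and schema errors are explicit", {
  gen <- tiny_cohort(8, K = 2, seed = 2)
  f <- tempfile(fileext = ".csv")
  write_panel(gen$panel, f)
  back <- read_panel(f)
  expect_identical(back$status, gen$panel$status)
  expect_equal(back, gen$panel)
  ## drop a mandatory column
  broken <- gen$panel[, setdiff(names(gen$panel), "status")]
  f2 <- tempfile(fileext = ".csv")
  utils::write.csv(broken, f2, row.names = FALSE)
  expect_error(read_panel(f2), "missing mandatory columns.*status")
  ## ground truth round-trip
  f3 <- tempfile(fileext = ".csv")
  write_ground_truth(gen$truth, f3)
  tt <- read_ground_truth(f3)
  expect_equal(tt$true_state, gen$truth$true_state)
})
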