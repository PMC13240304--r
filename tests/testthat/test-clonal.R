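test_that("total efficacy is the fraction-weighted mean of clone efficacies", {
  pop <- example_populations("two_clone_beneficial")
  # per-clone: 1-(1-0.24)(0.7) = 0.468 and 1-(1-0.64)(0.9) = 0.676
  expect_equal(total_efficacy(pop), 0.5 * 0.468 + 0.5 * 0.676,
               tolerance = 1e-12)
  pop3 <- example_populations("three_clone_sequential")
  expect_equal(total_efficacy(pop3), (0.816 + 0.82 + 0.856) / 3,
               tolerance = 1e-12)
  mono <- example_populations("monoclonal_conditional")
  plan <- cycle_plan(drug_on = TRUE, d = 0.4)
  expect_equal(total_efficacy(mono, plan),
               combined_efficacy(clone_params(0.7, 0.4, 0.5), drug_spec(0.4)),
               tolerance = 1e-12)
})

test_that("total efficacy lies between the extreme clone efficacies", {
  set.seed(10)
  for (i in 1:50) {
    pop <- random_population(sample(2:6, 1))
    plan <- cycle_plan(drug_on = TRUE, d = runif(1), alpha = runif(1))
    e <- vapply(pop$clones, function(cl) {
      combined_efficacy(cl$params, drug_spec(plan$d, plan$alpha))
    }, numeric(1))
    et <- total_efficacy(pop, plan)
    expect_gte(et, min(e) - 1e-12)
    expect_lte(et, max(e) + 1e-12)
  }
})

test_that("priority weights reweight the objective", {
  pop3 <- clone_population(
    clone("C1", 1 / 3, clone_params(0.9, 0.6, 0.4), priority_weight = 0.5),
    clone("C2", 1 / 3, clone_params(0.8, 0.7, 0.5), priority_weight = 0.25),
    clone("C3", 1 / 3, clone_params(0.7, 0.8, 0.6), priority_weight = 0.25)
  )
  expect_equal(weighted_efficacy(pop3),
               0.5 * 0.816 + 0.25 * 0.82 + 0.25 * 0.856, tolerance = 1e-12)
  # weights equal to fractions recover the total objective
  popf <- clone_population(
    clone("C1", 0.3, clone_params(0.9, 0.6, 0.4), priority_weight = 0.3),
    clone("C2", 0.7, clone_params(0.8, 0.7, 0.5), priority_weight = 0.7)
  )
  expect_equal(weighted_efficacy(popf), total_efficacy(popf),
               tolerance = 1e-12)
  # all weight on one clone: its efficacy alone
  pop1 <- clone_population(
    clone("C1", 0.5, clone_params(0.9, 0.6, 0.4), priority_weight = 1),
    clone("C2", 0.5, clone_params(0.8, 0.7, 0.5), priority_weight = 0)
  )
  expect_equal(weighted_efficacy(pop1), 0.816, tolerance = 1e-12)
  expect_error(weighted_efficacy(example_populations("two_clone_beneficial")),
               class = "samclone_missing_weights")
})

test_that("fraction update implements the selection law", {
  pop3 <- example_populations("three_clone_sequential")
  up <- update_fractions(pop3, c(0.816, 0.82, 0.856))
  f <- vapply(up$clones, `[[`, numeric(1), "fraction")
  expect_equal(f, (1 / 3) * c(1 - 0.816, 1 - 0.82, 1 - 0.856) /
                 (1 - (0.816 + 0.82 + 0.856) / 3), tolerance = 1e-12)
  expect_equal(round(f, 5), c(0.36220, 0.35433, 0.28346))
  # equal efficacies leave fractions untouched
  same <- update_fractions(pop3, rep(0.5, 3))
  expect_equal(vapply(same$clones, `[[`, numeric(1), "fraction"),
               rep(1 / 3, 3), tolerance = 1e-12)
  # eradicated clone vanishes
  two <- clone_population(clone("A", 0.5, clone_params(0.5, 0.1, 0.1)),
                          clone("B", 0.5, clone_params(0.5, 0.1, 0.1)))
  gone <- update_fractions(two, c(1, 0))
  expect_equal(vapply(gone$clones, `[[`, numeric(1), "fraction"), c(0, 1))
  expect_error(update_fractions(two, c(1, 1)),
               class = "samclone_eradication")
})

test_that("fraction update conserves mass and selects against hard-hit clones", {
  set.seed(11)
  for (i in 1:100) {
    pop <- random_population(sample(2:8, 1))
    e <- runif(length(pop$clones), 0, 0.95)
    f0 <- vapply(pop$clones, `[[`, numeric(1), "fraction")
    et <- sum(f0 * e)
    f1 <- vapply(update_fractions(pop, e)$clones, `[[`, numeric(1),
                 "fraction")
    expect_equal(sum(f1), 1, tolerance = 1e-9)
    grow <- e < et - 1e-12
    shrink <- e > et + 1e-12
    expect_true(all(f1[grow] > f0[grow]))
    expect_true(all(f1[shrink] < f0[shrink]))
  }
})

test_that("a monoclonal population is a fixed point of the update", {
  mono <- example_populations("monoclonal_high_samhd1")
  expect_equal(update_fractions(mono, 0.5)$clones[[1]]$fraction, 1)
})

test_that("regimen simulation tracks burden as the product of per-cycle survival", {
  pop3 <- example_populations("three_clone_sequential")
  tr <- simulate_regimen(pop3, cycle_plan(), n_cycles = 1)
  expect_equal(tr$burden, 1 - (0.816 + 0.82 + 0.856) / 3, tolerance = 1e-12)
  tr5 <- simulate_regimen(pop3, cycle_plan(), n_cycles = 5)
  expect_equal(tr5$burden[5], prod(1 - tr5$e_total), tolerance = 1e-12)
  expect_true(all(diff(tr5$burden) <= 1e-15))
  # fractions sum to 1 each cycle
  sums <- tapply(tr5$table$fraction_after, tr5$table$cycle, sum)
  expect_equal(as.numeric(sums), rep(1, 5), tolerance = 1e-9)
  # inert treatment: nothing happens
  inert <- clone_population(clone("A", 0.4, clone_params(0, 0, 0)),
                            clone("B", 0.6, clone_params(0, 0, 0)))
  tri <- simulate_regimen(inert, cycle_plan(drug_on = TRUE, d = 1),
                          n_cycles = 3)
  expect_equal(tri$burden, rep(1, 3))
  expect_equal(tri$table$fraction_after, tri$table$fraction_before)
  # eradication ends the trace with burden 0
  lethal <- clone_population(clone("A", 1, clone_params(1, 0, 0)))
  trl <- simulate_regimen(lethal, cycle_plan(), n_cycles = 4)
  expect_true(trl$eradicated)
  expect_equal(trl$burden, 0)
  expect_equal(length(trl$e_total), 1)
})

test_that("a strong inhibitor on the final cycle beats ara-C alone for the shifted population", {
  pop3 <- example_populations("three_clone_sequential")
  off5 <- simulate_regimen(pop3, cycle_plan(), n_cycles = 5)
  plans <- c(rep(list(cycle_plan()), 4),
             list(cycle_plan(drug_on = TRUE, d = 1)))
  mixed <- simulate_regimen(pop3, plans)
  expect_lt(mixed$burden[5], off5$burden[5])
})

test_that("five-cycle burden with the drug crosses below ara-C-only near d = 1", {
  pop3 <- example_populations("three_clone_sequential")
  burden5 <- function(d) {
    plans <- c(rep(list(cycle_plan()), 4),
               list(cycle_plan(drug_on = TRUE, d = d)))
    simulate_regimen(pop3, plans)$burden[5]
  }
  b_off <- simulate_regimen(pop3, cycle_plan(), n_cycles = 5)$burden[5]
  d_grid <- seq(0.05, 1, by = 0.05)
  better <- vapply(d_grid, burden5, numeric(1)) < b_off
  # benefit only in a contiguous high-d band ending at d = 1
  expect_true(better[length(better)])
  expect_false(better[1])
  expect_equal(sum(diff(better) != 0), 1) # single crossing
  expect_gt(min(d_grid[better]), 0.8)
})

test_that("minimum drug-free cycles before the inhibitor pays off", {
  pop3 <- example_populations("three_clone_sequential")
  expect_equal(min_cycles_until_drug_beneficial(pop3, d = 1), 4)
  expect_equal(min_cycles_until_drug_beneficial(
    example_populations("two_clone_beneficial"), d = 0.3), 0)
  expect_true(is.na(min_cycles_until_drug_beneficial(pop3, d = 0,
                                                     max_cycles = 10)))
  lethal <- clone_population(clone("A", 0.5, clone_params(1, 0, 0)),
                             clone("B", 0.5, clone_params(1, 0.5, 0)))
  expect_error(min_cycles_until_drug_beneficial(lethal, d = 0.5),
               class = "samclone_eradication")
})

test_that("greedy next-cycle choice follows the per-cycle objective", {
  pop3 <- example_populations("three_clone_sequential")
  cands <- list(cycle_plan(drug_on = FALSE),
                cycle_plan(drug_on = TRUE, d = 1))
  pick0 <- optimize_next_cycle(pop3, cands)
  expect_equal(pick0$index, 1) # ara-C alone wins on the initial mix
  expect_equal(pick0$score, total_efficacy(pop3), tolerance = 1e-12)
  shifted <- simulate_regimen(pop3, cycle_plan(),
                              n_cycles = 4)$final_population
  pick4 <- optimize_next_cycle(shifted, cands)
  expect_equal(pick4$index, 2) # consistent with min-cycles = 4
  one <- optimize_next_cycle(pop3, cands[2])
  expect_identical(one$plan, cands[[2]])
  # exact tie: earliest candidate wins
  tie <- optimize_next_cycle(pop3, list(cycle_plan(), cycle_plan()))
  expect_equal(tie$index, 1)
})

test_that("per-clone drug-efficacy overrides take precedence over the plan", {
  pop <- clone_population(
    clone("resist", 0.5, clone_params(0.8, 0.3, 0.7),
          drug_efficacy_override = 0),
    clone("naive", 0.5, clone_params(0.8, 0.1, 0.2))
  )
  plan <- cycle_plan(drug_on = TRUE, d = 1)
  e1 <- base_efficacy(clone_params(0.8, 0.3, 0.7))      # override d_i = 0
  e2 <- combined_efficacy(clone_params(0.8, 0.1, 0.2), drug_spec(1))
  expect_equal(total_efficacy(pop, plan), 0.5 * (e1 + e2), tolerance = 1e-12)
})

test_that("dose labels switch the per-clone (x, z) pair", {
  pop <- clone_population(clone(
    "C1", 1, clone_params(0.5, 0.2, 0.5),
    dose_params = list(high = list(x = 0.9, z = 0.3))
  ))
  expect_equal(total_efficacy(pop, cycle_plan(dose_label = "high")),
               base_efficacy(clone_params(0.9, 0.2, 0.3)), tolerance = 1e-12)
  expect_error(total_efficacy(pop, cycle_plan(dose_label = "unknown")),
               class = "samclone_schema")
})

test_that("drug efficacy is recovered exactly from noise-free fraction shifts", {
  pop <- example_populations("two_clone_conditional")
  tr <- simulate_regimen(pop, cycle_plan(drug_on = TRUE, d = 0.5))
  post <- tr$table$fraction_after
  fit <- fit_drug_efficacy(pop, post)
  expect_lt(abs(fit$d - 0.5), 1e-6)
  expect_lt(fit$residual, 1e-12)
})

test_that("drug efficacy is recovered within 0.02 from binomially sampled fractions", {
  pop <- example_populations("two_clone_conditional")
  traj <- gen_clone_trajectory(pop, cycle_plan(drug_on = TRUE, d = 0.7),
                               K = 1e6, seed = 1)
  fit <- fit_drug_efficacy(pop, traj$fraction_observed)
  expect_lt(abs(fit$d - 0.7), 0.02)
})

test_that("identical clones leave the drug efficacy unidentifiable", {
  twin <- clone_population(clone("A", 0.5, clone_params(0.6, 0.3, 0.4)),
                           clone("B", 0.5, clone_params(0.6, 0.3, 0.4)))
  expect_warning(fit <- fit_drug_efficacy(twin, c(0.5, 0.5)),
                 class = "samclone_non_identifiable")
  expect_false(fit$identifiable)
  expect_true(is.na(fit$d))
})

test_that("population construction enforces fractions, weights and unique ids", {
  expect_error(clone_population(clone("A", 0.5, clone_params(0.5, 0.5, 0.5)),
                                clone("B", 0.6, clone_params(0.5, 0.5, 0.5))),
               class = "samclone_fraction_sum")
  norm <- clone_population(clone("A", 1, clone_params(0.5, 0.5, 0.5)),
                           clone("B", 1, clone_params(0.5, 0.5, 0.5)),
                           normalise = TRUE)
  expect_equal(vapply(norm$clones, `[[`, numeric(1), "fraction"),
               c(0.5, 0.5))
  expect_error(clone_population(clone("A", 0.5, clone_params(0.5, 0.5, 0.5)),
                                clone("A", 0.5, clone_params(0.5, 0.5, 0.5))),
               class = "samclone_duplicate_ids")
  expect_error(clone_population(
    clone("A", 0.5, clone_params(0.5, 0.5, 0.5), priority_weight = 0.5),
    clone("B", 0.5, clone_params(0.5, 0.5, 0.5))
  ), class = "samclone_invalid_parameter")
})
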