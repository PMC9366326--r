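# tiny 3-reaction chain: IN -> A -> OUT with A balanced
chain_network <- function() {
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  rf <- file.path(dir, "r.tsv"); mf <- file.path(dir, "m.tsv")
  writeLines(c("id\tname\tequation\tkind\tsubsystem",
               "EX_IN\tin\t-> NUTR\texchange\ttransport-in",
               "T\tt\tNUTR -> A\tinterconversion\ttransport-in",
               "R\tr\tA -> OUT\tinterconversion\tglycolysis",
               "ACC_OUT\tacc\tOUT <->\texchange\tbiomass sink"), rf)
  writeLines(c("id\tname\tcarbon_count\trole",
               "NUTR\tnutrient\t1\tnutrient",
               "A\tintermediate\t1\tinternal",
               "OUT\tproduct\t1\taccumulated"), mf)
  load_network(rf, mf)
}

test_that("assembly pins measured accumulation exchanges and sets bounds", {
  net <- chain_network()
  pr <- assemble_problem(net, data.frame(metabolite = "OUT", flux = 2), t = 6)
  expect_s3_class(pr, "fx_problem")
  expect_equal(pr$b_fix, c(ACC_OUT = 2))
  expect_equal(unname(pr$lb[c("EX_IN", "T", "R")]), c(0, 0, 0))
  expect_equal(unname(pr$lb["ACC_OUT"]), -pr$settings$big_bound)

  # negative accumulation (net breakdown) is carried through with its sign
  pr2 <- assemble_problem(net, data.frame(metabolite = "OUT", flux = -1), t = 6)
  expect_equal(pr2$b_fix, c(ACC_OUT = -1))

  expect_error(
    assemble_problem(net, data.frame(metabolite = "NOPE", flux = 1), t = 2),
    class = "fx_no_exchange")
})

test_that("forced chain carries the pinned flux through every reaction", {
  net <- chain_network()
  pr <- assemble_problem(net, data.frame(metabolite = "OUT", flux = 2), t = 6)
  sol <- solve_min_norm(pr)
  expect_identical(sol$status, "optimal")
  expect_equal(unname(sol$v_opt), rep(2, 4), tolerance = 1e-9)
  expect_equal(sol$objective, 16, tolerance = 1e-8)
  expect_lt(sol$steady_state_residual, 1e-8)
})

test_that("minimum norm splits symmetric parallel branches equally", {
  dir <- withr::local_tempdir()
  rf <- file.path(dir, "r.tsv"); mf <- file.path(dir, "m.tsv")
  writeLines(c("id\tname\tequation\tkind\tsubsystem",
               "EX_IN\tin\t-> NUTR\texchange\ttransport-in",
               "T\tt\tNUTR -> A\tinterconversion\ttransport-in",
               "B1\tb1\tA -> OUT\tinterconversion\tglycolysis",
               "B2\tb2\tA -> OUT\tinterconversion\tglycolysis",
               "ACC_OUT\tacc\tOUT <->\texchange\tbiomass sink"), rf)
  writeLines(c("id\tname\tcarbon_count\trole",
               "NUTR\tn\t1\tnutrient", "A\ta\t1\tinternal",
               "OUT\to\t1\taccumulated"), mf)
  net <- load_network(rf, mf)
  pr <- assemble_problem(net, data.frame(metabolite = "OUT", flux = 2), t = 2)
  sol <- solve_min_norm(pr)
  expect_equal(unname(sol$v_opt[c("B1", "B2")]), c(1, 1), tolerance = 1e-9)
})

test_that("doubling all accumulation constraints doubles the solution", {
  scen <- default_plantain_scenario()
  net <- scen$network
  ct <- truth_constraints(scen, weeks = 6)
  ct1 <- ct[ct$cultivar == "AG", ]
  s1 <- solve_min_norm(assemble_problem(net, ct1, t = 6))
  ct2 <- ct1; ct2$flux <- 2 * ct2$flux
  s2 <- solve_min_norm(assemble_problem(net, ct2, t = 6))
  expect_equal(unname(s2$v_opt), 2 * unname(s1$v_opt), tolerance = 1e-6)
})

test_that("infeasible problems name the conflicting constraints; relaxation recovers", {
  net <- chain_network()
  # OUT must accumulate at 2 but the only route is capped below that
  settings <- solver_settings(big_bound = 1)
  pr <- assemble_problem(net, data.frame(metabolite = "OUT", flux = 2), t = 4,
                         settings = settings)
  err <- tryCatch(solve_min_norm(pr), fx_infeasible = function(e) e)
  expect_s3_class(err, "fx_infeasible")

  rel <- relax_and_diagnose(pr, weight = 1e6)
  expect_identical(rel$status, "relaxed")
  expect_equal(rel$slack_report$constraint[1], "ACC_OUT")
  expect_lt(rel$v_opt[["ACC_OUT"]], 2)  # pulled toward the cap

  # on a consistent problem the relaxation matches the hard solve
  pr_ok <- assemble_problem(net, data.frame(metabolite = "OUT", flux = 0.5),
                            t = 4, settings = settings)
  hard <- solve_min_norm(pr_ok)
  soft <- relax_and_diagnose(pr_ok, weight = 1e8)
  expect_lt(max(abs(hard$v_opt - soft$v_opt)), 1e-4)
  expect_lt(max(abs(soft$slack_report$slack)), 1e-4)
})

test_that("a corrupted constraint owns the slack under weighted relaxation", {
  # A -> OUT1 + OUT2 forces equal accumulation of the two products; inflating
  # one measured flux by 50% makes the equalities inconsistent
  dir <- withr::local_tempdir()
  rf <- file.path(dir, "r.tsv"); mf <- file.path(dir, "m.tsv")
  writeLines(c("id\tname\tequation\tkind\tsubsystem",
               "EX_IN\tin\t-> NUTR\texchange\ttransport-in",
               "T\tt\tNUTR -> A\tinterconversion\ttransport-in",
               "R\tr\tA -> OUT1 + OUT2\tinterconversion\tglycolysis",
               "ACC_OUT1\tacc1\tOUT1 <->\texchange\tbiomass sink",
               "ACC_OUT2\tacc2\tOUT2 <->\texchange\tbiomass sink"), rf)
  writeLines(c("id\tname\tcarbon_count\trole",
               "NUTR\tn\t2\tnutrient", "A\ta\t2\tinternal",
               "OUT1\to1\t1\taccumulated", "OUT2\to2\t1\taccumulated"), mf)
  net <- load_network(rf, mf)

  ct <- data.frame(metabolite = c("OUT1", "OUT2"), flux = c(2, 3)) # +50%
  pr <- assemble_problem(net, ct, t = 2)
  expect_error(solve_min_norm(pr), class = "fx_infeasible")

  # the corrupted, down-weighted constraint absorbs nearly all the slack
  rel <- relax_and_diagnose(pr, weight = c(ACC_OUT1 = 1e6, ACC_OUT2 = 1e2))
  tot <- sum(abs(rel$slack_report$slack))
  own <- abs(rel$slack_report$slack[rel$slack_report$constraint == "ACC_OUT2"])
  expect_gte(own / tot, 0.9)
})

test_that("series solving records isolated failures and errors only when all fail", {
  net <- chain_network()
  ct <- data.frame(week = c(2, 6), metabolite = "OUT", flux = c(0.5, 5))
  ser <- solve_series(net, ct, solver_settings(big_bound = 1))
  expect_length(ser$failures, 1L)
  expect_false(is.null(ser$solutions[["2"]]))
  expect_true(is.null(ser$solutions[["6"]]))

  ct_bad <- data.frame(week = c(2, 6), metabolite = "OUT", flux = c(5, 5))
  expect_error(solve_series(net, ct_bad, solver_settings(big_bound = 1)),
               class = "fx_all_infeasible")

  ser1 <- solve_series(net, data.frame(week = 4, metabolite = "OUT",
                                       flux = 0.2))
  expect_length(ser1$weeks, 1L)
})

test_that("edge tables flip reversed reactions and carry widths", {
  net <- chain_network()
  sol <- solve_min_norm(
    assemble_problem(net, data.frame(metabolite = "OUT", flux = 2), t = 2))
  em <- export_flux_map(sol, net)
  expect_equal(nrow(em), 4L)
  expect_equal(em$width, rep(2, 4))

  # net breakdown: a fully reversible chain runs backwards
  dir <- withr::local_tempdir()
  rf <- file.path(dir, "r.tsv"); mf <- file.path(dir, "m.tsv")
  writeLines(c("id\tname\tequation\tkind\tsubsystem",
               "EX_IN\tin\tNUTR <->\texchange\ttransport-in",
               "T\tt\tNUTR <-> A\tinterconversion\ttransport-in",
               "R\tr\tA <-> OUT\tinterconversion\tglycolysis",
               "ACC_OUT\tacc\tOUT <->\texchange\tbiomass sink"), rf)
  writeLines(c("id\tname\tcarbon_count\trole",
               "NUTR\tn\t1\tnutrient", "A\ta\t1\tinternal",
               "OUT\to\t1\taccumulated"), mf)
  net2 <- load_network(rf, mf)
  sol2 <- solve_min_norm(
    assemble_problem(net2, data.frame(metabolite = "OUT", flux = -1), t = 2))
  em2 <- export_flux_map(sol2, net2)
  row <- em2[em2$reaction == "ACC_OUT", ]
  expect_equal(row$flux, -1, tolerance = 1e-9)
  expect_equal(row$width, 1, tolerance = 1e-9)
  expect_equal(row$to, "OUT")   # direction flipped: material re-enters
})

test_that("equality-only random instances match the pseudoinverse closed form end to end", {
  for (seed in 1:10) {
    inst <- random_eq_instance(n_met = 5, n_rxn = 10, seed = seed)
    sol <- solve_qp_box(w = 1, E = inst$E, d = inst$d, lb = -Inf, ub = Inf)
    ref <- oracle_least_norm(inst$E, inst$d)
    expect_lt(max(abs(sol$v - ref)), 1e-7 * max(1, max(abs(ref))))
  }
})
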