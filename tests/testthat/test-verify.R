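test_that("audit flags exactly the defined indicator violations", {
  cfg <- gapfill_config()  # B_l = 1e-3, B_u = 3000
  expect_true(audit_solution(list(s = c(C1 = 1), f = c(C1 = 5)), cfg)$clean)
  rep1 <- audit_solution(list(s = c(C1 = 0), f = c(C1 = 5)), cfg)
  expect_false(rep1$clean)
  expect_identical(rep1$violations$bound, "lower")
  # flux below the active bound is not a violation for an unselected reaction
  expect_true(audit_solution(list(s = c(C1 = 0), f = c(C1 = 5e-4)), cfg)$clean)
  # flux above B_u on a selected reaction violates the upper bound
  rep2 <- audit_solution(list(s = c(C1 = 1), f = c(C1 = 3001)), cfg)
  expect_identical(rep2$violations$bound, "upper")
  expect_error(audit_solution(list(s = c(C1 = 0), f = c(C2 = 1)), cfg),
               "missing s or f")
})

test_that("audit matches its definition on randomized MILP states", {
  cfg <- gapfill_config()
  withr::with_seed(42, {
    for (k in 1:40) {
      n <- sample(1:8, 1)
      ids <- paste0("C", seq_len(n))
      s <- stats::setNames(sample(0:1, n, replace = TRUE), ids)
      f <- stats::setNames(stats::runif(n, 0, 2) *
                             10^sample(-4:3, n, replace = TRUE), ids)
      rep <- audit_solution(list(s = s, f = f), cfg)
      expected <- (s == 0 & abs(f) >= cfg$B_l) |
        (s == 1 & abs(f) > cfg$B_u + 1e-9)
      expect_setequal(rep$violations$reaction, ids[expected])
      expect_identical(rep$clean, !any(expected))
    }
  })
})

test_that("minimality verification removes the costlier redundant reaction", {
  # C1 and C2 are each individually sufficient; C2 (out-of-taxon, cost 4)
  # is tried first under descending-cost order and removed
  vm <- verify_minimality(toy3_model(), c("C1", "C2"), toy3_db())
  expect_identical(vm$minimal_set, "C1")
  expect_identical(vm$removed, "C2")
  vm2 <- verify_minimality(toy3_model(), "C1", toy3_db())
  expect_identical(vm2$minimal_set, "C1")
  expect_identical(vm2$removed, character(0))
  expect_error(verify_minimality(toy3_model(), "C3", toy3_db()),
               "does not enable growth")
})

test_that("minimality verification is idempotent and yields essential members", {
  for (i in 1:6) {
    bm <- test_benchmark(i, n_delete = 1, n_decoys = 2, n_redundant = 2)
    vm <- verify_minimality(bm$gapped, bm$padded_solution, bm$database)
    expect_true(all(vm$minimal_set %in% bm$padded_solution))
    again <- verify_minimality(bm$gapped, vm$minimal_set, bm$database)
    expect_identical(again$minimal_set, vm$minimal_set)
    expect_identical(again$removed, character(0))
    # essentiality: removing any single member kills growth
    for (id in vm$minimal_set) {
      reduced <- setdiff(vm$minimal_set, id)
      m <- add_reactions(bm$gapped, unname(bm$database[reduced]))
      expect_false(grows(m))
    }
  }
})

test_that("brute-force oracle enumerates in increasing cost", {
  bf <- brute_force_min_gapfill(toy3_model(), toy3_db(),
                                gapfill_config(allow_reversals = FALSE))
  expect_true(bf$feasible)
  expect_identical(bf$added, "C1")
  expect_equal(bf$cost, 2)
  m <- add_reactions(toy3_model(), reaction("C0", c(B = -1, Z = 1), "L2R"))
  expect_equal(brute_force_min_gapfill(m, toy3_db())$cost, 0)
  bf3 <- brute_force_min_gapfill(toy3_model(), toy3_db()[3],
                                 gapfill_config(allow_reversals = FALSE))
  expect_false(bf3$feasible)
  expect_true(is.na(bf3$cost))
  big_db <- lapply(1:21, function(k)
    reaction(paste0("D", k), stats::setNames(c(-1, 1), paste0("X", c(k, k + 1)))))
  expect_error(brute_force_min_gapfill(toy3_model(), big_db,
                                       gapfill_config(allow_reversals = FALSE)),
               "refuses")
})
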