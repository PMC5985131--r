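test_that("benchmark tabulates repeats, averages and ground-truth stats", {
  rec <- fix_record()
  tab <- run_benchmark(rec, n_repeats = 2, seed = 5)
  # 2 repeats x 2 methods + one averages row per method
  expect_equal(nrow(tab), 6)
  expect_true(all(c("total_iterations", "snr_eig", "snr_rms",
                    "Sens", "PPA", "F1") %in% names(tab)))
  avg <- tab[grepl("average", tab$method), ]
  expect_equal(nrow(avg), 2)
  per <- tab[!grepl("average", tab$method) & tab$method == "improved", ]
  expect_equal(avg$total_iterations[avg$method == "improved (average)"],
               mean(per$total_iterations))

  tab2 <- run_benchmark(rec, n_repeats = 2, seed = 5)
  expect_identical(tab$total_iterations, tab2$total_iterations)
  expect_identical(tab$F1, tab2$F1)
})

test_that("benchmark mean iterations: overrelaxed at most conventional", {
  rec <- fix_record()
  tab <- run_benchmark(rec, n_repeats = 5, seed = 9)
  mi <- tab$total_iterations[tab$method == "improved (average)"]
  mc <- tab$total_iterations[tab$method == "conventional (average)"]
  expect_lte(mi, mc)
})
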