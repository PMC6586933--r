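test_that("profiles condition tastant responses on ATP viability", {
  calls <- rbind(
    make_calls("a", c("Ringer", "ATP", "denatonium", "saccharin"),
               c(FALSE, TRUE, FALSE, FALSE), 1:4),
    make_calls("b", c("Ringer", "ATP", "denatonium", "saccharin"),
               c(FALSE, TRUE, TRUE, TRUE), 1:4),
    make_calls("c", c("Ringer", "ATP", "denatonium", "saccharin"),
               c(FALSE, FALSE, FALSE, FALSE), 1:4))
  prof <- build_profiles(calls)
  expect_equal(prof$profile_key[prof$cell_id == "a"], "")
  expect_true(prof$atp_responsive[prof$cell_id == "a"])
  expect_equal(prof$profile_key[prof$cell_id == "b"],
               "denatonium+saccharin")
  expect_false(prof$atp_responsive[prof$cell_id == "c"])

  # excluded cells are dropped entirely
  excl <- make_calls("d", c("Ringer", "ATP"), c(FALSE, TRUE), 1:2,
                     exclusion = "ringer_responsive")
  prof2 <- build_profiles(rbind(calls, excl))
  expect_false("d" %in% prof2$cell_id)
})

test_that("frequency tables reproduce counts, percents and partitions", {
  prof <- make_profiles(c("denatonium", "", "denatonium+saccharin"),
                        c(30, 60, 10), n_nonviable = 25)
  ft <- frequency_table(prof, c("denatonium", "saccharin"))
  via <- ft[ft$kind == "viability", ]
  expect_equal(via$count, 100); expect_equal(via$denominator, 125)
  den <- ft[ft$label == "denatonium" & ft$kind == "compound", ]
  expect_equal(den$count, 40)
  expect_equal(den$percent, 40)
  # profile rows partition the cells responding to >= 1 compound
  pr <- ft[ft$kind == "profile", ]
  expect_equal(sum(pr$count), 40)
  expect_true(all(pr$denominator == 40))
  expect_true(all(ft$percent <= 100))
  expect_equal(ft$percent, 100 * ft$count / ft$denominator)

  none <- make_profiles("", 10)
  ft0 <- frequency_table(none, "denatonium")
  expect_equal(ft0$count[ft0$label == "denatonium"], 0)
  expect_error(frequency_table(prof[0, ], "denatonium"), "empty")
})

test_that("venn counts partition pairwise responders", {
  prof <- make_profiles(c("denatonium", "sucralose",
                               "denatonium+sucralose", ""),
                             c(99, 1, 8, 50))
  v <- venn_counts(prof, "denatonium", "sucralose")
  expect_equal(v, list(only_a = 99, only_b = 1, both = 8, total = 108))
  expect_equal(v$only_a + v$only_b + v$both, v$total)

  v0 <- venn_counts(make_profiles("", 5), "denatonium", "sucralose")
  expect_equal(v0$total, 0)
})

test_that("retention counts match cells responsive in both phases", {
  ids <- sprintf("c%02d", 1:10)
  before <- make_calls(ids, "denatonium", c(rep(TRUE, 8), FALSE, FALSE))
  after <- make_calls(ids, "denatonium",
                      c(rep(TRUE, 6), FALSE, FALSE, TRUE, FALSE))
  r <- retention_counts(before, after, "denatonium")
  expect_equal(r$n_total, 8)
  expect_equal(r$n_retained, 6)
  # all retained
  r2 <- retention_counts(before, before, "denatonium")
  expect_equal(r2, list(n_retained = 8, n_total = 8, fraction = 1))
  # swapping phases changes the denominator to the after-responsive set
  r3 <- retention_counts(after, before, "denatonium")
  expect_equal(r3$n_total, 7)
  expect_error(retention_counts(before[-1, ], after, "denatonium"),
               "matching error")
})

test_that("dose-response normalizes within cell to the reference dose", {
  calls <- rbind(make_calls("a", rep("denatonium", 2), TRUE, 1:2,
                            peak_dff = c(0.2, 0.4)),
                 make_calls("b", rep("denatonium", 2), TRUE, 1:2,
                            peak_dff = c(0.3, 0.5)))
  calls$concentration_mM <- rep(c(1, 10), 2)
  dr <- dose_response(calls, "denatonium")
  expect_equal(dr$reference_concentration, 10)
  a <- dr$per_cell[dr$per_cell$cell_id == "a", ]
  expect_equal(a$normalized_peak, c(0.5, 1))
  expect_equal(dr$summary$mean[dr$summary$concentration_mM == 10], 1)
  expect_equal(dr$summary$mean[dr$summary$concentration_mM == 1],
               mean(c(0.5, 0.6)))
  # a cell without a responsive reference call is dropped with a warning
  calls$responsive[4] <- FALSE
  expect_warning(dr2 <- dose_response(calls, "denatonium"), "dropped")
  expect_false("b" %in% dr2$per_cell$cell_id)
})

test_that("repeated stimulations are normalized to the first response", {
  calls <- rbind(make_calls("a", rep("denatonium", 2), TRUE, 1:2,
                            peak_dff = c(0.4, 0.4)),
                 make_calls("b", rep("denatonium", 2), c(TRUE, FALSE), 1:2,
                            peak_dff = c(0.4, 0.1)))
  nf <- normalize_to_first(calls, "denatonium")
  expect_equal(nf$normalized_peak[nf$cell_id == "a"], c(1, 1))
  expect_equal(nf$normalized_peak[nf$cell_id == "b"], c(1, 0.25))
  expect_true(all(nf$normalized_peak[nf$stimulation == 1] == 1))

  bad <- make_calls("c", rep("denatonium", 2), c(FALSE, TRUE), 1:2)
  expect_warning(nf2 <- normalize_to_first(rbind(calls, bad), "denatonium"),
                 "non-responsive")
  expect_false("c" %in% nf2$cell_id)
})

test_that("blocked second responses separate from controls by U-test", {
  # PLC-inhibitor-like condition: second response scaled to 5% of the first
  set.seed(10)
  first <- pmax(0.2, rnorm(10, 0.8, 0.2))
  control <- pmax(0.05, rnorm(10, 0.95, 0.1))   # repeat-stimulation ratio
  blocked <- control * 0.05
  u <- mann_whitney_u(blocked[1:8], control[1:8])
  expect_lt(u$p_value, 0.01)
  expect_gt(median(blocked), 0.02)
  expect_lt(median(blocked), 0.1)
})

test_that("heat-map rows group by profile with boundary indices", {
  time <- seq(0, 380, by = 0.5)
  n <- 5
  dff <- matrix(0, n, length(time))
  for (i in 1:n) dff[i, ] <- make_transient(time, 131, 2, 12, 0.1 * i)
  norm <- structure(list(time = time, dff = dff, f0 = rep(1, n),
                         cell_ids = paste0("c", 1:n),
                         schedule = default_schedule(), recording = NULL,
                         bleach_fit = NULL, corrected = FALSE),
                    class = "ca_normalized")
  prof <- data.frame(cell_id = paste0("c", 1:n),
                     atp_responsive = TRUE,
                     responded_to = c("denatonium", "denatonium",
                                      "denatonium", "saccharin", "saccharin"),
                     profile_key = c("denatonium", "denatonium",
                                     "denatonium", "saccharin", "saccharin"),
                     stringsAsFactors = FALSE)
  hm <- heatmap_matrix(norm, prof)
  expect_equal(hm$boundaries, 3)
  expect_equal(hm$groups, c(rep("denatonium", 3), rep("saccharin", 2)))
  # within a group, rows sort by amplitude descending
  expect_equal(rownames(hm$matrix)[1:3], c("c3", "c2", "c1"))

  # row order is stable under permutation of the input cells
  perm <- c(4, 1, 5, 3, 2)
  norm2 <- norm
  norm2$dff <- dff[perm, ]
  norm2$cell_ids <- norm$cell_ids[perm]
  hm2 <- heatmap_matrix(norm2, prof)
  expect_equal(rownames(hm2$matrix), rownames(hm$matrix))

  empty <- heatmap_matrix(norm, prof[0, ])
  expect_equal(nrow(empty$matrix), 0)
})
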