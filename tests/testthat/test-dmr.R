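test_that("cluster_dmps follows the sliding-window scan rules", {
  # singleton excluded
  expect_equal(nrow(cluster_dmps(make_dmps(100, "methylated"), 400)), 0L)

  # anchor at 100 includes 150, re-anchors at 150 (covers to 550); 700 is
  # out of reach and ends up a dropped singleton
  cl <- cluster_dmps(make_dmps(c(100, 150, 700), rep("methylated", 3)), 400)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$members[[1]], c(100L, 150L))
  expect_equal(cl$start, 100L)
  expect_equal(cl$end, 151L)

  # chain of four: every consecutive gap (300) within the 400 bp window
  cl2 <- cluster_dmps(make_dmps(c(0, 300, 600, 900), rep("methylated", 4)),
                      400)
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$n_dmps, 4L)

  # an opposite-direction DMP inside the window terminates the cluster
  cl3 <- cluster_dmps(make_dmps(c(0, 100, 200, 300, 400),
                                c("methylated", "methylated", "de-methylated",
                                  "methylated", "methylated")), 400)
  expect_equal(nrow(cl3), 2L)
  expect_equal(cl3$direction, c("methylated", "methylated"))
  expect_equal(cl3$members[[1]], c(0L, 100L))
  expect_equal(cl3$members[[2]], c(300L, 400L))

  # skip mode chains each direction independently
  cl4 <- cluster_dmps(make_dmps(c(0, 100, 200, 300, 400),
                                c("methylated", "methylated", "de-methylated",
                                  "methylated", "methylated")), 400,
                      opposite = "skip")
  expect_equal(sort(cl4$n_dmps), 4L)
  expect_error(cluster_dmps(make_dmps(c(100, 50), c("methylated",
                                                    "methylated"))[2:1, ],
                            400), "sorted")
})

test_that("cluster_dmps equals the brute-force chain oracle", {
  set.seed(53)
  for (i in 1:200) {
    n <- sample(1:50, 1)
    pos <- sort(sample(0:5000, n))
    dir <- sample(c("methylated", "de-methylated"), n, replace = TRUE)
    L <- sample(c(50, 100, 300, 700, 1500), 1)
    got <- cluster_dmps(make_dmps(pos, dir), L)
    want <- oracle_chain(pos, dir, L)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$members, unclass(lapply(want, `[[`, "members")),
                   ignore_attr = TRUE)
      expect_equal(got$direction, vapply(want, `[[`, "", "direction"))
    }
  }
})

test_that("window growth never shrinks same-direction chains", {
  set.seed(59)
  for (i in 1:20) {
    pos <- sort(sample(0:4000, 30))
    d1 <- cluster_dmps(make_dmps(pos, rep("methylated", 30)), 200,
                       min_cluster_size = 1)
    d2 <- cluster_dmps(make_dmps(pos, rep("methylated", 30)), 500,
                       min_cluster_size = 1)
    expect_lte(nrow(d2), nrow(d1))
    # every small-window cluster is contained in one large-window cluster
    for (k in seq_len(nrow(d1))) {
      inside <- vapply(d2$members, function(m)
        all(d1$members[[k]] %in% m), TRUE)
      expect_equal(sum(inside), 1L)
    }
  }
})

test_that("test_clusters pools members and matches a 2x2 oracle", {
  # maximal separation -> significant methylated DMR
  rel <- rbind(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0))
  r <- make_relmeth(rel, pos = c(100L, 200L))
  cl <- cluster_dmps(make_dmps(c(100, 200), rep("methylated", 2)), 400)
  dmr <- test_clusters(cl, r)
  expect_equal(nrow(dmr), 1L)
  expect_equal(dmr$direction, "methylated")
  expect_equal(c(dmr$start, dmr$end), c(100L, 201L))
  expect_equal(dmr$n_dmps, 2L)

  # pooled test statistic equals an independently computed 2x2 LRT
  set.seed(61)
  rel2 <- rbind(pmin(pmax(c(0.55, 0.6, 0.5, 0.45, 0.5, 0.4) +
                            runif(6, -0.1, 0.1), 0), 1),
                pmin(pmax(c(0.6, 0.5, 0.55, 0.4, 0.45, 0.5) +
                            runif(6, -0.1, 0.1), 0), 1))
  r2 <- make_relmeth(rel2, pos = c(100L, 200L))
  dmr2 <- test_clusters(cl, r2, overdispersion = "none", return_all = TRUE)
  numC <- round(rel2 * 100)
  g_want <- oracle_g2x2(sum(numC[, 1:3]), 600, sum(numC[, 4:6]), 600)
  expect_equal(dmr2$region_p,
               pchisq(g_want, 1, lower.tail = FALSE), tolerance = 1e-12)

  # member absent from the matrix is a data error
  r3 <- make_relmeth(rel[1, , drop = FALSE], pos = 100L)
  expect_error(test_clusters(cl, r3), "absent")
})

test_that("optimize_window scans the grid and breaks ties at the smallest length", {
  # strongly separated relmeth so every cluster is significant
  pos <- seq(0L, by = 500L, length.out = 5L)
  r <- make_relmeth(matrix(rep(c(1, 1, 1, 0, 0, 0), 5), ncol = 6,
                           byrow = TRUE), pos = pos)
  dmps <- make_dmps(pos, rep("methylated", 5))
  ws <- optimize_window(dmps, r, lengths = seq(100, 2000, by = 100))
  expect_equal(ws$chosen_length, 500L)
  expect_equal(ws$scan$n_dmrs[ws$scan$length < 500], rep(0L, 4))
  expect_true(all(ws$scan$n_dmrs[ws$scan$length >= 500] == 1L))

  # pair 50 bp apart: every candidate works; tie -> smallest (100)
  r2 <- make_relmeth(matrix(rep(c(1, 1, 1, 0, 0, 0), 2), ncol = 6,
                            byrow = TRUE), pos = c(100L, 150L))
  ws2 <- optimize_window(make_dmps(c(100, 150), rep("methylated", 2)), r2)
  expect_equal(ws2$chosen_length, 100L)

  # empty DMP list -> smallest candidate, flagged
  ws3 <- optimize_window(make_dmps(integer(), character()), r2)
  expect_true(ws3$empty)
  expect_equal(ws3$chosen_length, 100L)
  expect_equal(sum(ws3$scan$n_dmrs), 0L)
})

test_that("published window-length defaults are exposed", {
  expect_equal(default_window_lengths("FVS"),
               c(CG = 900L, CHG = 1000L, CHH = 700L, `6mA` = 400L))
  expect_equal(default_window_lengths("AVS")[["CG"]], 1000L)
  expect_equal(default_window_lengths("AVF")[["CHH"]], 900L)
})

test_that("DMR outputs respect direction consistency and disjoint spans", {
  set.seed(67)
  n <- 60
  pos <- sort(sample(seq(0, 20000, by = 10), n))
  dir <- sample(c("methylated", "de-methylated"), n, replace = TRUE)
  rel <- matrix(0, n, 6)
  rel[dir == "methylated", 1:3] <- 0.9
  rel[dir == "de-methylated", 4:6] <- 0.9
  rel <- rel + matrix(runif(n * 6, 0, 0.05), n, 6)
  r <- make_relmeth(rel, pos = pos)
  run <- call_dmrs(make_dmps(pos, dir), r, window_length = 600)
  dmrs <- run$dmrs
  if (nrow(dmrs) > 1) {
    for (dd in unique(dmrs$direction)) {
      sub <- dmrs[dmrs$direction == dd, ]
      if (nrow(sub) > 1) {
        sub <- sub[order(sub$start), ]
        expect_true(all(sub$start[-1] >= sub$end[-nrow(sub)]))
      }
    }
  }
  # member directions equal the cluster direction by construction of the scan
  for (k in seq_len(nrow(dmrs))) {
    member_dirs <- dir[match(dmrs$members[[k]], pos)]
    expect_equal(unique(member_dirs), dmrs$direction[k])
  }
})
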