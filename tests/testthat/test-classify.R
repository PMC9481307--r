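# brute-force re-statement of the grading rules, written directly from the
# interval table and the majority/priority text; kept independent of the
# package's vote/classify code paths
oracle_classify <- function(v) {
  inb <- c(v[1] >= 1 & v[1] < 5, v[2] >= 10 & v[2] < 100,
           v[3] >= 0.01 & v[3] < 0.1, v[4] >= 0.01 & v[4] < 0.1, v[5] > 35)
  inp <- c(v[1] >= 5 & v[1] < 10, v[2] >= 100 & v[2] < 200,
           v[3] >= 0.1 & v[3] < 0.2, v[4] >= 0.1 & v[4] < 0.2,
           v[5] >= 15 & v[5] <= 35)
  ine <- c(v[1] >= 10, v[2] >= 200, v[3] >= 0.2, v[4] >= 0.2, v[5] < 15)
  if (v[2] < 10 && v[1] < 1) return("normal")
  counts <- c(bulge = sum(inb), protrusion = sum(inp), extrusion = sum(ine))
  if (max(counts) >= 3) return(names(counts)[which.max(counts)])
  for (k in 1:5) {
    if (inb[k]) return("bulge")
    if (inp[k]) return("protrusion")
    if (ine[k]) return("extrusion")
  }
  "normal"
}

test_that("each grade's all-in-range vector gets five votes and wins", {
  vb <- indicator_votes(c(3, 50, 0.05, 0.05, 40))
  expect_equal(unname(vb$counts["bulge"]), 5L)
  vp <- indicator_votes(c(7, 150, 0.15, 0.15, 25))
  expect_equal(unname(vp$counts["protrusion"]), 5L)
  ve <- indicator_votes(c(12, 250, 0.25, 0.25, 10))
  expect_equal(unname(ve$counts["extrusion"]), 5L)
  expect_equal(classify_herniation(c(3, 50, 0.05, 0.05, 40))$label, "bulge")
  expect_equal(classify_herniation(c(7, 150, 0.15, 0.15, 25))$label, "protrusion")
  expect_equal(classify_herniation(c(12, 250, 0.25, 0.25, 10))$label, "extrusion")
  # below every geometric range only the gray indicator votes
  v1 <- indicator_votes(c(0.5, 5, 0.005, 0.005, 40))
  expect_equal(sum(v1$counts), 1L)
  expect_equal(unname(v1$counts["bulge"]), 1L)
})

test_that("every interval boundary votes for exactly one grade", {
  boundary_vectors <- list(
    distance = list(c(5, 0, 0, 0, 100), c(10, 0, 0, 0, 100)),
    area = list(c(0, 100, 0, 0, 100), c(0, 200, 0, 0, 100)),
    length_ratio = list(c(0, 0, 0.1, 0, 100), c(0, 0, 0.2, 0, 100)),
    area_ratio = list(c(0, 0, 0, 0.1, 100), c(0, 0, 0, 0.2, 100)))
  for (ind in names(boundary_vectors)) for (v in boundary_vectors[[ind]]) {
    per <- indicator_votes(v)$per_indicator
    expect_true(per[[ind]] %in% c("protrusion", "extrusion"))
  }
  # gray boundaries: 35 and 15 both belong to protrusion
  expect_equal(unname(indicator_votes(c(0, 0, 0, 0, 35))$per_indicator["mean_gray"]),
               "protrusion")
  expect_equal(unname(indicator_votes(c(0, 0, 0, 0, 15))$per_indicator["mean_gray"]),
               "protrusion")
  expect_equal(unname(indicator_votes(c(5, 0, 0, 0, 100))$per_indicator["distance"]),
               "protrusion")
  expect_equal(unname(indicator_votes(c(10, 0, 0, 0, 100))$per_indicator["distance"]),
               "extrusion")
})

test_that("the decision path: tiny protrusion, majority, priority tie-break", {
  d0 <- classify_herniation(c(0, 0, 0, 0, 40))
  expect_equal(d0$label, "normal")
  expect_equal(d0$decided_by, "normal_rule")
  # mixed votes: extrusion 1 (distance), protrusion 3 (area, area ratio, gray)
  dm <- classify_herniation(c(12, 150, 0.05, 0.15, 25))
  expect_equal(unname(dm$votes), c(1L, 3L, 1L))
  expect_equal(dm$label, "protrusion")
  expect_equal(dm$decided_by, "majority")
  # 2/2/1 split resolved by the first voting indicator (distance)
  dt <- classify_herniation(c(1, 210, 0.21, 0.16, 40))
  expect_true(max(dt$votes) < 3)
  expect_equal(dt$decided_by, "priority_tiebreak")
  expect_equal(dt$label, "bulge")
})

test_that("classification agrees with the brute-force oracle on 10000 vectors", {
  t0 <- proc.time()[["elapsed"]]
  withr::with_seed(4242, {
    n <- 10000L
    vs <- cbind(runif(n, 0, 15), runif(n, 0, 300), runif(n, 0, 0.3),
                runif(n, 0, 1), runif(n, 0, 255))
    # sprinkle exact boundary values to stress the interval conventions
    bnd <- list(c(1, 5, 10), c(10, 100, 200), c(0.01, 0.1, 0.2),
                c(0.01, 0.1, 0.2), c(15, 35, 35))
    for (j in 1:5) {
      hit <- sample(n, 600)
      vs[hit, j] <- sample(bnd[[j]], 600, replace = TRUE)
    }
    mism <- 0L
    for (i in seq_len(n)) {
      if (classify_herniation(vs[i, ])$label != oracle_classify(vs[i, ]))
        mism <- mism + 1L
    }
    expect_equal(mism, 0L)
  })
  expect_lt(proc.time()[["elapsed"]] - t0, 30)
})

test_that("severity is not monotone under the printed tie-break (regression)", {
  # the tie-break can demote a more severe vector; pin the behaviour
  lo <- classify_herniation(c(0.9, 150, 0.15, 0.15, 40))
  hi <- classify_herniation(c(1.0, 210, 0.21, 0.16, 40))
  expect_equal(lo$label, "protrusion")
  expect_equal(hi$label, "bulge")
})

test_that("batch classification merges flags and survives JSON round-trips", {
  vecs <- list(c(3, 50, 0.05, 0.05, 40), c(0, 0, 0, 0, 18))
  out <- batch_classify(vecs, degenerated = c(FALSE, TRUE), canal_continuous = TRUE)
  expect_length(out$discs, 2L)
  expect_false(out$discs[[1]]$degenerated)
  expect_true(out$discs[[2]]$degenerated)
  expect_true(out$canal$continuous)
  expect_error(batch_classify(vecs, degenerated = TRUE, canal_continuous = TRUE),
               "same length")
  empty <- batch_classify(list(), logical(0), canal_continuous = FALSE)
  expect_length(empty$discs, 0L)
  expect_false(empty$canal$continuous)
})
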