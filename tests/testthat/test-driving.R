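# Driving classification and overlap counts.

test_that("the four driver combinations map to the four categories", {
  ratio <- rep(TRUE, 4)
  cbf <- c(TRUE, FALSE, TRUE, FALSE)
  nodal <- c(FALSE, TRUE, TRUE, FALSE)
  cl <- classifyDriving(ratio, cbf, nodal, regions = letters[1:4])
  expect_equal(as.character(cl$category),
               c("CBF_only", "NODE_only", "BOTH", "RATIO_only"))
  expect_equal(cl$region, letters[1:4])
})

test_that("regions without ratio significance are never classified", {
  expect_equal(nrow(classifyDriving(rep(FALSE, 6), rep(TRUE, 6),
                                    rep(TRUE, 6))), 0)
  ratio <- c(TRUE, FALSE, TRUE)
  cl <- classifyDriving(ratio, c(TRUE, TRUE, FALSE), c(FALSE, TRUE, FALSE))
  expect_equal(cl$region, c("1", "3"))
  expect_error(classifyDriving(c(TRUE, TRUE), TRUE, c(TRUE, TRUE)),
               "length")
})

test_that("categories partition the ratio-significant set (random masks)", {
  set.seed(50)
  for (rep in 1:20) {
    n <- 90
    ratio <- runif(n) < 0.3
    cbf <- runif(n) < 0.3
    nodal <- runif(n) < 0.3
    cl <- classifyDriving(ratio, cbf, nodal)
    expect_equal(nrow(cl), sum(ratio))
    expect_false(any(duplicated(cl$region)))
    # set-algebra oracle for the counts
    counts <- table(cl$category)
    expect_equal(unname(counts[["CBF_only"]]), sum(ratio & cbf & !nodal))
    expect_equal(unname(counts[["NODE_only"]]), sum(ratio & !cbf & nodal))
    expect_equal(unname(counts[["BOTH"]]), sum(ratio & cbf & nodal))
    expect_equal(unname(counts[["RATIO_only"]]), sum(ratio & !cbf & !nodal))
  }
})

test_that("overlap counts satisfy inclusion-exclusion on random masks", {
  set.seed(51)
  for (rep in 1:20) {
    n <- 60
    c0 <- runif(n) < 0.4; d0 <- runif(n) < 0.4; r0 <- runif(n) < 0.4
    ov <- overlapCounts(c0, d0, r0)
    expect_equal(ov$total_cbf,
                 ov$cbf_only + ov$cbf_nodal + ov$cbf_ratio + ov$all_three)
    expect_equal(ov$total_nodal,
                 ov$nodal_only + ov$cbf_nodal + ov$nodal_ratio + ov$all_three)
    expect_equal(ov$total_ratio,
                 ov$ratio_only + ov$cbf_ratio + ov$nodal_ratio + ov$all_three)
    # brute-force region-by-region tally
    expect_equal(ov$all_three, sum(c0 & d0 & r0))
    expect_equal(ov$cbf_only, sum(c0 & !d0 & !r0))
  }
  # disjoint and identical masks
  ovD <- overlapCounts(c(TRUE, FALSE, FALSE), c(FALSE, TRUE, FALSE),
                       c(FALSE, FALSE, TRUE))
  expect_equal(ovD$all_three + ovD$cbf_nodal + ovD$cbf_ratio +
               ovD$nodal_ratio, 0)
  ovI <- overlapCounts(rep(TRUE, 5), rep(TRUE, 5), rep(TRUE, 5))
  expect_equal(ovI$all_three, 5)
  expect_equal(ovI$cbf_only + ovI$nodal_only + ovI$ratio_only, 0)
})

test_that("injected effects are recovered into their driving categories", {
  # small replicate study: hyperperfusion-only regions should classify
  # CBF_only, disconnection-only regions NODE_only, in most replicates
  nRep <- 8
  hits <- matrix(0, nRep, 2)
  sets <- defaultRegionSets(90L)
  hyperOnly <- setdiff(sets$hyperperfusion, sets$disconnection)
  discOnly <- setdiff(sets$disconnection, sets$hyperperfusion)
  for (r in seq_len(nRep)) {
    cfg <- cohortConfig(nPatients = 45L, nControls = 40L, nRegions = 90L,
                        nTimepoints = 100L, seed = 600L + r)
    res <- suppressMessages(runPipeline(cfg, outDir = withr::local_tempdir(),
                                        metrics = "DC"))
    regions <- rownames(res$cohort)
    cls <- setNames(as.character(res$driving$category), res$driving$region)
    asgn <- function(set, want) {
      got <- cls[regions[set]]
      mean(!is.na(got) & got == want)  # unclassified counts as a miss
    }
    hits[r, 1] <- asgn(hyperOnly, "CBF_only")
    hits[r, 2] <- asgn(discOnly, "NODE_only")
  }
  expect_gt(mean(hits[, 1]), 0.7)
  expect_gt(mean(hits[, 2]), 0.7)
})
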