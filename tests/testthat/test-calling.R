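fx <- table2_fixture()

golden_status <- c(`5` = "POSITIVE", `6` = "REVIEW", `8` = "NEGATIVE",
                   `15` = "POSITIVE", `16` = "FAILED_RNA", `22` = "POSITIVE",
                   `24` = "POSITIVE", `24C` = "FAILED_ASSAY",
                   `IVS-020` = "POSITIVE")
golden_fusion <- c(`5` = "RUNX1::RUNX1T1", `15` = "RBM15::MKL1",
                   `22` = "EBF1::PDGFRB", `24` = "TCF3::PBX1",
                   `IVS-020` = "PML::RARA")

test_that("probe scoring applies strict cutoffs to the worked example", {
  calls5 <- score_probes(fixture_sample(fx, "5"), fx$calibration, fx$manifest)
  r <- calls5[calls5$probe_id == "RUNX1(ex6):RUNX1T1(ex2)", ]
  expect_equal(r$status, "POSITIVE")
  expect_equal(r$count, 373)
  expect_equal(sum(calls5$status == "POSITIVE"), 1L)

  calls6 <- score_probes(fixture_sample(fx, "6"), fx$calibration, fx$manifest)
  r <- calls6[calls6$probe_id == "CBFB(ex5):MYH11 (type A)(ex33)", ]
  expect_equal(r$status, "REVIEW")
  expect_equal(r$count, 23)
  expect_equal(sum(calls6$status %in% c("REVIEW", "POSITIVE")), 1L)
})

test_that("counts exactly at a cutoff take the lower status", {
  m <- tiny_manifest(1)
  pid <- "GENE1(ex1):PART1(ex2)"
  calib <- calibration_table(data.frame(probe_id = pid, cut3 = 21, cut5 = 28))
  status_at <- function(count) {
    lane <- make_lane(m, fusion = stats::setNames(count, pid))
    score_probes(lane, calib, m)$status
  }
  expect_equal(status_at(28), "REVIEW")     # = cut5 is not positive
  expect_equal(status_at(29), "POSITIVE")
  expect_equal(status_at(21), "NEGATIVE")   # = cut3 is not review
  expect_equal(status_at(22), "REVIEW")
})

test_that("probe scoring agrees with a brute-force re-scan on random lanes", {
  m <- tiny_manifest(8)
  fus <- probe_ids(m, "FUSION")
  set.seed(2024)
  for (i in 1:200) {
    cut3 <- runif(length(fus), 5, 40)
    cut5 <- cut3 + runif(length(fus), 0, 20)
    uncal <- runif(length(fus)) < 0.1
    cut3[uncal] <- NA; cut5[uncal] <- NA
    calib <- calibration_table(data.frame(probe_id = fus, cut3 = cut3,
                                          cut5 = cut5))
    cnt <- sample(c(0:60, NA), length(fus), replace = TRUE)
    lane <- make_lane(m, fusion = stats::setNames(cnt, fus))
    got <- score_probes(lane, calib, m)
    want <- vapply(seq_along(fus), function(j)
      oracle_probe_status(cnt[j], cut3[j], cut5[j], !uncal[j]), "")
    expect_identical(got$status, want)
  }
})

test_that("the worked-example run reproduces the template interpretation row", {
  interps <- interpret_run(fx$samples, fx$calibration, fx$manifest)
  expect_equal(vapply(interps, `[[`, "", "status"), golden_status)
  for (id in names(golden_fusion)) {
    expect_equal(unique(interps[[id]]$positive_fusions$fusion_id),
                 unname(golden_fusion[id]), label = paste("lane", id))
  }
  expect_equal(unique(interps[["6"]]$review_fusions$fusion_id), "CBFB::MYH11")
  expect_equal(interps[["16"]]$recommendation, "REPEAT_MORE_RNA")
  expect_equal(interps[["24C"]]$recommendation, "REPEAT_MORE_RNA")
  expect_equal(nrow(interps[["24C"]]$positive_fusions), 0L)
})

test_that("assay failure voids fusion calls regardless of counts", {
  # graft the collapsed 24C ladder onto every lane: all must void
  ladder_24c <- fixture_sample(fx, "24C")$counts[fx$manifest$pos_control_ids]
  for (s in fx$samples) {
    s$counts[fx$manifest$pos_control_ids] <- ladder_24c
    interp <- interpret_sample(s, fx$calibration, fx$manifest)
    expect_equal(interp$status, "FAILED_ASSAY")
    expect_equal(nrow(interp$positive_fusions), 0L)
  }
})

test_that("a positive call survives inadequate RNA, with a note", {
  lane <- fixture_sample(fx, "22")
  hk <- probe_ids(fx$manifest, "HOUSEKEEPING")
  lane$counts[hk] <- 1L
  interp <- interpret_sample(lane, fx$calibration, fx$manifest)
  expect_equal(interp$status, "POSITIVE")
  expect_match(paste(interp$notes, collapse = "; "), "RNA quality inadequate")
})

test_that("diffuse elevation across many fusions is high background", {
  lane <- fixture_sample(fx, "8")
  fus <- probe_ids(fx$manifest, "FUSION")
  lane$counts[fus] <- 200L  # above every cut5; 11 distinct fusions
  interp <- interpret_sample(lane, fx$calibration, fx$manifest)
  expect_equal(interp$status, "HIGH_BACKGROUND")
  expect_equal(interp$recommendation, "REPEAT_LESS_RNA")
})

test_that("a lane with most fusion probes missing is not interpretable", {
  lane <- fixture_sample(fx, "8")
  fus <- probe_ids(fx$manifest, "FUSION")
  lane$counts[fus[1:7]] <- NA_integer_
  interp <- interpret_sample(lane, fx$calibration, fx$manifest)
  expect_equal(interp$status, "NOT_INTERPRETABLE")
})

test_that("increasing one fusion count never demotes a positive lane", {
  lane <- fixture_sample(fx, "5")
  for (bump in c(1L, 50L, 5000L)) {
    lane2 <- lane
    lane2$counts[["RUNX1(ex6):RUNX1T1(ex2)"]] <-
      lane$counts[["RUNX1(ex6):RUNX1T1(ex2)"]] + bump
    expect_equal(interpret_sample(lane2, fx$calibration, fx$manifest)$status,
                 "POSITIVE")
  }
})

test_that("interpretation is deterministic", {
  a <- interpret_run(fx$samples, fx$calibration, fx$manifest)
  b <- interpret_run(fx$samples, fx$calibration, fx$manifest)
  expect_identical(a, b)
})

test_that("reflex mode recommends the second tube only on a clean negative", {
  cfg <- call_config(reflex = TRUE)
  interps <- interpret_run(fx$samples, fx$calibration, fx$manifest, cfg)
  expect_equal(interps[["8"]]$recommendation, "REFLEX_HEME2")
  expect_equal(interps[["16"]]$recommendation, "REPEAT_MORE_RNA")
  expect_true(reflex_decision(interps[["8"]]))
  for (id in setdiff(names(interps), "8")) {
    expect_false(reflex_decision(interps[[id]]), label = paste("lane", id))
  }
  heme2 <- interps[["8"]]
  heme2$tube <- "HEME2"
  expect_error(reflex_decision(heme2), "HEME1", class = "calling_error")
})

test_that("concordance compares called fusions to the flow immunophenotype", {
  interps <- interpret_run(fx$samples, fx$calibration, fx$manifest)
  expect_equal(check_concordance(interps[["IVS-020"]], "AML", fx$manifest),
               "CONCORDANT")   # PML::RARA is a promyelocytic AML fusion
  expect_equal(check_concordance(interps[["IVS-020"]], "T-ALL", fx$manifest),
               "DISCORDANT")
  expect_equal(check_concordance(interps[["8"]], "NONE_DETECTED", fx$manifest),
               "CONCORDANT")
  expect_equal(check_concordance(interps[["8"]], "B-ALL", fx$manifest),
               "NOT_ASSESSABLE")
  expect_equal(check_concordance(interps[["16"]], "AML", fx$manifest),
               "NOT_ASSESSABLE")
  expect_equal(check_concordance(interps[["24C"]], "AML", fx$manifest),
               "NOT_ASSESSABLE")
})

test_that("BCR::ABL1 concordance accepts both of its lineages", {
  lane <- fixture_sample(fx, "8")
  lane$counts[["BCR(ex1):ABL1(ex3)"]] <- 500L
  interp <- interpret_sample(lane, fx$calibration, fx$manifest)
  expect_equal(interp$status, "POSITIVE")
  expect_equal(check_concordance(interp, "B-ALL", fx$manifest), "CONCORDANT")
  expect_equal(check_concordance(interp, "CML", fx$manifest), "CONCORDANT")
  expect_equal(check_concordance(interp, "AML", fx$manifest), "DISCORDANT")
  # a brute-force scan over the whole lineage map agrees
  for (fid in names(fx$manifest$lineage_map)) {
    for (lin in LINEAGE_LEVELS) {
      lane2 <- fixture_sample(fx, "8")
      probe <- fx$manifest$probes$probe_id[
        !is.na(fx$manifest$probes$fusion_id) &
          fx$manifest$probes$fusion_id == fid][1]
      lane2$counts[[probe]] <- 5000L
      got <- check_concordance(
        interpret_sample(lane2, fx$calibration, fx$manifest), lin,
        fx$manifest)
      want <- if (lin %in% fx$manifest$lineage_map[[fid]])
        "CONCORDANT" else "DISCORDANT"
      expect_equal(got, want, label = paste(fid, lin))
    }
  }
})
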