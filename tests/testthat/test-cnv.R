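test_that("reciprocal overlap computes per-base fractions", {
  a <- make_seg(start = 100, end = 200)
  expect_equal(reciprocal_overlap(a, a),
               list(overlap_bp = 100, frac_a = 1, frac_b = 1))

  b <- make_seg(start = 150, end = 350)
  ro <- reciprocal_overlap(a, b)
  expect_equal(ro$overlap_bp, 50)
  expect_equal(ro$frac_a, 0.5)
  expect_equal(ro$frac_b, 0.25)
  # fails the 50% reciprocal rule on b's side
  expect_false(ro$frac_a >= 0.5 && ro$frac_b >= 0.5)

  expect_equal(reciprocal_overlap(a, make_seg(start = 300, end = 400))$overlap_bp, 0)
  expect_equal(reciprocal_overlap(a, make_seg(chrom = "2", start = 100,
                                              end = 200)),
               list(overlap_bp = 0, frac_a = 0, frac_b = 0))
})

test_that("overlap is symmetric", {
  set.seed(2)
  for (i in 1:50) {
    a <- random_profile(1)
    b <- random_profile(1)
    expect_equal(reciprocal_overlap(a, b)$overlap_bp,
                 reciprocal_overlap(b, a)$overlap_bp)
  }
})

test_that("adjacent copy of a tumor gain matches; germline events are vetoed", {
  tumor <- make_seg(start = 1e6, end = 1e6 + 150000, seg_mean = 0.8)
  adjacent <- make_seg(start = 1e6, end = 1e6 + 150000, seg_mean = 0.4)
  m <- match_adjacent_to_tumor(adjacent, tumor)
  expect_equal(nrow(m), 1)
  expect_equal(m$overlap_bp, 150000)

  m2 <- match_adjacent_to_tumor(adjacent, tumor, blood = adjacent)
  expect_equal(nrow(m2), 0)

  # near-neutral blood segments (genome-tiling remainder) never veto
  neutral_blood <- make_seg(start = 0, end = 1e8, seg_mean = 0.02)
  m3 <- match_adjacent_to_tumor(adjacent, tumor, blood = neutral_blood)
  expect_equal(nrow(m3), 1)
})

test_that("amplitude filter and sign concordance gate candidates", {
  tumor <- make_seg(start = 0, end = 1000, seg_mean = 0.5)
  faint <- make_seg(start = 0, end = 1000, seg_mean = 0.1)  # not > 0.1
  expect_equal(nrow(match_adjacent_to_tumor(faint, tumor)), 0)
  loss <- make_seg(start = 0, end = 1000, seg_mean = -0.4)
  expect_equal(nrow(match_adjacent_to_tumor(loss, tumor)), 0)
  expect_equal(nrow(match_adjacent_to_tumor(
    loss, tumor, require_sign_concordance = FALSE)), 1)
})

test_that("matching equals the per-base brute-force oracle on random profiles", {
  set.seed(14)
  for (i in 1:150) {
    adj <- random_profile(sample(0:12, 1))
    tum <- random_profile(sample(1:12, 1))
    bld <- if (runif(1) < 0.5) random_profile(sample(1:5, 1)) else NULL
    got <- match_adjacent_to_tumor(adj, tum, bld)
    want <- oracle_match(adj, tum, bld)
    expect_equal(got[, c("adj_idx", "tumor_idx", "overlap_bp")],
                 want, ignore_attr = TRUE)
  }
})

test_that("shared-bp tiers reproduce the printed ranges", {
  mk <- function(bp) data.frame(adj_idx = 1, tumor_idx = 1, chrom = "1",
                                start = 0, end = bp, overlap_bp = bp)
  expect_equal(classify_cn(mk(150000), "triplet")$category, "evidence_of_tumor")
  expect_equal(classify_cn(mk(100000), "triplet")$category, "evidence_of_tumor")
  expect_equal(classify_cn(mk(99999), "triplet")$category, "small_evidence")
  expect_equal(classify_cn(mk(50000), "triplet")$category, "small_evidence")
  expect_equal(classify_cn(mk(1000), "triplet")$category, "small_evidence")
  expect_equal(classify_cn(mk(500), "triplet")$category, "normal")
  expect_equal(classify_cn(mk(0)[0, ], "triplet")$category, "normal")
  expect_equal(classify_cn(mk(150000), "pair")$category, "likely_evidence")
  expect_equal(classify_cn(mk(50000), "pair")$category, "normal")
})

test_that("splitting an adjacent segment never increases shared bp", {
  tumor <- make_seg(start = 0, end = 1000, seg_mean = 0.6)
  whole <- make_seg(start = 0, end = 1000, seg_mean = 0.3)
  halves <- make_seg(start = c(0, 500), end = c(500, 1000),
                     seg_mean = c(0.3, 0.3))
  bp_whole <- sum(match_adjacent_to_tumor(whole, tumor)$overlap_bp)
  bp_halves <- sum(match_adjacent_to_tumor(halves, tumor)$overlap_bp)
  expect_equal(bp_whole, 1000)
  # halves still meet the reciprocal rule exactly at 50%, conserving bp
  expect_equal(bp_halves, 1000)
  # thirds fall below 50% of the tumor segment and can only lose bp
  thirds <- make_seg(start = c(0, 333, 666), end = c(333, 666, 1000),
                     seg_mean = 0.3)
  bp_thirds <- sum(match_adjacent_to_tumor(thirds, tumor)$overlap_bp)
  expect_lte(bp_thirds, bp_whole)
  expect_equal(bp_thirds, 0)
  # but halves matching matched tumor halves conserve shared bp
  tumor_halves <- make_seg(start = c(0, 500), end = c(500, 1000),
                           seg_mean = c(0.6, 0.6))
  expect_equal(sum(match_adjacent_to_tumor(halves, tumor_halves)$overlap_bp),
               1000)
})

test_that("cohort screen errors on pair mode with blood present", {
  trip <- simulate_segments(sim_config(n_patients = 1, cn_contamination = 1,
                                       adjacent_vaf_scale = 0.5,
                                       germline_cnv = TRUE, seed = 5), 1)
  expect_error(cnv_screen(list(P1 = trip), mode = "pair"), "pair mode")
  expect_silent(cnv_screen(list(P1 = trip[c("tumor", "adjacent")],
                                P2 = trip[c("tumor", "adjacent")]),
                           mode = "pair"))
})
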