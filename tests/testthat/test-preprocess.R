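test_that("patches are centred on their spot and padded by reflection", {
  b <- small_bundle()
  p <- 32L
  pat <- extract_patches(b, p)
  expect_equal(nrow(pat$x), nrow(b$grid))
  # centre pixel of the patch equals the image pixel at (px_y, px_x)
  for (s in c(1, 17, 55)) {
    patch <- array(pat$x[s, ], c(p, p, 3))
    cy <- round(b$grid$px_y[s]); cx <- round(b$grid$px_x[s])
    expect_equal(patch[p / 2 + 1, p / 2 + 1, ],
                 b$image[cy + 1, cx + 1, ])
  }
  # a patch of side 2 x spot radius contains the whole capture disc:
  # the patch equals the image crop spanning the disc bounding box
  pd <- extract_patches(b, 36L)
  s <- 17
  cy <- round(b$grid$px_y[s]); cx <- round(b$grid$px_x[s])
  crop <- b$image[cy + 1 + seq.int(-18, 17), cx + 1 + seq.int(-18, 17), ]
  expect_equal(array(pd$x[s, ], c(36, 36, 3)), crop)

  # corner spot on a margin-less grid still yields a full-size patch
  g <- make_hex_grid(4, 4, pitch_px = 40, spot_diameter_px = 20,
                     margin_px = 12)
  lat <- simulate_expression(g, n_genes = 4, seed = 2)
  img <- render_slide(g, lat, seed = 3)
  bb <- slide_bundle(g, img, lat$counts, lat, "met", "corner")
  pat2 <- extract_patches(bb, 64)
  expect_equal(dim(pat2$x), c(16L, 64L * 64L * 3L))
  expect_error(extract_patches(bb, 512), "larger than image")
  expect_error(extract_patches(bb, 31), "even")
})

test_that("patch extraction is translation-consistent", {
  b <- small_bundle()
  shift <- 7L
  H <- dim(b$image)[1]; W <- dim(b$image)[2]
  img2 <- array(0, dim(b$image) + c(shift, shift, 0))
  img2[shift + seq_len(H), shift + seq_len(W), ] <- b$image
  g2 <- b$grid
  g2$px_x <- g2$px_x + shift; g2$px_y <- g2$px_y + shift
  b2 <- b; b2$image <- img2; b2$grid <- g2
  expect_equal(extract_patches(b, 32)$x, extract_patches(b2, 32)$x)
})

test_that("dichotomization uses a strict median cut per gene", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(0, 0, 0, 5), c = c(2, 2, 2, 2))
  bt <- dichotomize(m)
  expect_equal(unname(bt$labels[, "a"]), c(0, 0, 1, 1))
  expect_equal(unname(bt$labels[, "b"]), c(0, 0, 0, 1))
  # constant gene: all negative, flagged degenerate
  expect_equal(unname(bt$labels[, "c"]), c(0, 0, 0, 0))
  expect_true(bt$degenerate["c"])
  expect_false(bt$degenerate["a"])
  expect_equal(unname(bt$medians), c(2.5, 0, 2))
})

test_that("continuous values give balanced labels in [0.4, 0.5]", {
  set.seed(5)
  for (n in c(41, 100, 257)) {
    v <- matrix(rgamma(n * 3, 2), n, 3)
    bt <- dichotomize(v)
    frac <- colMeans(bt$labels)
    expect_true(all(frac >= 0.4 & frac <= 0.5))
  }
})

test_that("gene selection ranks by mean FSV with lexicographic ties", {
  cohort <- mini_cohort()
  genes <- colnames(cohort[[1]]$counts)
  # k = n_genes returns a permutation of all genes
  all_sel <- select_genes(cohort, k = length(genes))
  expect_setequal(all_sel, genes)
  expect_error(select_genes(cohort, k = 0), "positive")

  # two identical constant genes: order falls back to gene id
  g <- make_hex_grid(5, 5, pitch_px = 64, spot_diameter_px = 36)
  cnt <- matrix(3L, 25, 2, dimnames = list(g$spot_id, c("zz", "aa")))
  b <- slide_bundle(g, NULL, cnt, NULL, "met", "t")
  expect_equal(select_genes(list(b), 2), c("aa", "zz"))
})

test_that("strongly spatial genes outrank noise genes across seeds", {
  g <- make_hex_grid(12, 12, pitch_px = 64, spot_diameter_px = 36)
  wins <- 0L
  for (s in 1:10) {
    des <- make_gene_design(n_genes = 2, sv_fraction = 0.5,
                            contextual_fraction = 0,
                            group_differential_fraction = 0, seed = s)
    des$loading[des$sv_flag] <- 1.2
    lat <- simulate_expression(g, seed = 100 + s, design = des)
    b <- slide_bundle(g, NULL, lat$counts, lat, "met", "t")
    sel <- select_genes(list(b), 2)
    sv_gene <- des$gene_id[des$sv_flag]
    wins <- wins + (sel[1] == sv_gene)
  }
  expect_gte(wins, 9L)
})
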