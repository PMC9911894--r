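test_that("worked scoring examples reproduce the published point sums", {
  # solid isoechoic oval smooth, no foci: 2 + 1 = 3
  a <- tirads_points("solid", "isoechoic", "oval_or_round",
                     "smooth_or_regular", "none")
  expect_equal(a$points, 3)
  expect_equal(unlist(a[1, 1:5]),
               c(composition = 2, echogenicity = 1, shape = 0, margins = 0,
                 echogenic_foci = 0))

  # mixed cystic/solid scored on its isoechoic solid component: 1 + 1; the
  # lexicon assigns punctate foci 3 points, so with microcalcifications the
  # total is 5 (TR4), not the 3 sometimes quoted from an undercount of foci
  b <- tirads_points("mixed_cystic_solid", "isoechoic", "oval_or_round",
                     "smooth_or_regular", "microcalcification")
  expect_equal(unlist(b[1, 1:5]),
               c(composition = 1, echogenicity = 1, shape = 0, margins = 0,
                 echogenic_foci = 3))
  expect_equal(b$points, 5)

  # all-zero features
  expect_equal(tirads_points("purely_cystic", "anechoic", "oval_or_round",
                             "smooth_or_regular", "none")$points, 0)

  # hand-summed worst case: 2 + 3 + 3 + 3 + 3 = 14, TR5
  d <- tirads_points("solid", "very_hypoechoic", "taller_than_wide",
                     "spiculated_sharp_angles", "microcalcification")
  expect_equal(d$points, 14)
  expect_equal(tirads_category(14), "TR5")

  # foci points accumulate over all foci present
  multi <- tirads_points("solid", "hypoechoic", "oval_or_round",
                         "smooth_or_regular",
                         list(c("macrocalcification", "microcalcification")))
  expect_equal(multi$echogenic_foci, 4)
})

test_that("point totals bin into the five TR categories", {
  expect_equal(tirads_category(c(0, 2, 3, 4, 5, 6, 7, 9, 20)),
               c("TR1", "TR2", "TR3", "TR4", "TR4", "TR4", "TR5", "TR5", "TR5"))
  expect_warning(one <- tirads_category(1), "TR1")
  expect_equal(one, "TR1")
  expect_error(tirads_category(-1), "nonnegative")
})

test_that("biopsy indication follows the per-category size thresholds", {
  expect_equal(tirads_fna_indication("TR5", 10), "fna_recommended")
  expect_equal(tirads_fna_indication("TR5", 9.9), "no_fna")
  expect_equal(tirads_fna_indication("TR4", c(14.9, 15)),
               c("no_fna", "fna_recommended"))
  expect_equal(tirads_fna_indication("TR3", 24), "no_fna")
  expect_equal(tirads_fna_indication("TR3", 25), "fna_recommended")
  expect_equal(tirads_fna_indication(c("TR1", "TR2"), c(60, 60)),
               c("no_fna", "no_fna"))
})

test_that("engine matches the naive oracle over the full descriptor grid", {
  grid <- us_feature_grid()
  eng <- tirads_points(grid$composition, grid$echogenicity, grid$shape,
                       grid$margins, grid$echogenic_foci)
  cat_eng <- suppressWarnings(tirads_category(eng$points))
  for (i in seq_len(nrow(grid))) {
    o <- naive_tirads(grid$composition[i], grid$echogenicity[i],
                      grid$shape[i], grid$margins[i], grid$echogenic_foci[i])
    if (o$points != eng$points[i] || o$category != cat_eng[i]) {
      fail(sprintf("grid cell %d disagrees with the oracle", i))
    }
  }
  succeed()
})

test_that("points and category are monotone in single-feature upgrades", {
  cfg <- tirads_config()
  grid <- us_feature_grid()
  set.seed(1)
  grid <- grid[sample(nrow(grid), 120), ]
  cat_rank <- function(x) match(x, c("TR1", "TR2", "TR3", "TR4", "TR5"))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, ]
    base <- tirads_points(row$composition, row$echogenicity, row$shape,
                          row$margins, row$echogenic_foci)$points
    base_cat <- suppressWarnings(tirads_category(base))
    for (f in c("composition", "echogenicity", "shape", "margins",
                "echogenic_foci")) {
      tab <- cfg$points[[f]]
      higher <- names(tab)[tab > tab[[row[[f]]]]]
      for (h in higher) {
        row2 <- row; row2[[f]] <- h
        p2 <- tirads_points(row2$composition, row2$echogenicity, row2$shape,
                            row2$margins, row2$echogenic_foci)$points
        expect_gte(p2, base)
        expect_gte(cat_rank(suppressWarnings(tirads_category(p2))),
                   cat_rank(base_cat))
      }
    }
  }
})

test_that("biopsy action is monotone in diameter at fixed category", {
  for (cat in c("TR3", "TR4", "TR5")) {
    d <- seq(4, 60, by = 0.5)
    act <- tirads_fna_indication(rep(cat, length(d)), d)
    pos <- act == "fna_recommended"
    # once positive, stays positive as diameter grows
    expect_true(all(diff(pos) >= 0))
  }
})
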