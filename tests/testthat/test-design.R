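test_that("packaged design returns the realized experiment per genotype", {
  for (g in c("Chandler", "Rayen")) {
    d <- packaged_design(g)
    expect_equal(nrow(d), 28)
    expect_setequal(d$treatment_id, c(as.character(1:27), "DKW"))
  }
  ch <- packaged_design("Chandler")
  # treatment 1 factor vector and proliferation summary
  r1 <- ch[ch$treatment_id == "1", ]
  expect_equal(unname(unlist(r1[paste0("X", 1:9)])),
               c(0.5, 2, 2, 2.5, 0.5, 0.5, 0.5, 2, 2))
  expect_equal(r1$PR_mean, 9.5)
  expect_equal(r1$PR_se, 0.18)
  # DKW control row
  dkw <- ch[ch$treatment_id == "DKW", ]
  expect_equal(unname(unlist(dkw[paste0("X", 1:9)])),
               c(rep(1, 8), 0.1))
  expect_equal(dkw$PR_mean, 7.12)
  # factor vectors identical across genotypes; summaries differ
  ra <- packaged_design("Rayen")
  expect_identical(ch[paste0("X", 1:9)], ra[paste0("X", 1:9)])
  expect_false(identical(ch$PR_mean, ra$PR_mean))
  # rows 12 and 13 are identical factor vectors with distinct summaries
  expect_equal(unlist(ra[ra$treatment_id == "12", paste0("X", 1:9)]),
               unlist(ra[ra$treatment_id == "13", paste0("X", 1:9)]))
  expect_false(ra$PR_mean[ra$treatment_id == "12"] ==
                 ra$PR_mean[ra$treatment_id == "13"])
  expect_error(packaged_design("Serr"))
})

test_that("packaged design is a pure fixture and stays on the level grid", {
  expect_identical(packaged_design("Chandler"), packaged_design("Chandler"))
  fd <- factor_definitions()
  d <- packaged_design("Chandler")
  for (j in 1:9) {
    lv <- unlist(fd[j, c("level1", "level2", "level3")])
    vals <- d[d$treatment_id != "DKW", paste0("X", j)]
    expect_true(all(vals %in% lv), label = paste("factor", j, "on grid"))
  }
  # the control sits off-grid only in X9
  dkw <- unlist(d[d$treatment_id == "DKW", paste0("X", 1:9)])
  expect_equal(unname(dkw[9]), 0.1)
})

test_that("generic L27 array is balanced and pairwise orthogonal", {
  arr <- build_l27_array()
  expect_equal(dim(arr), c(27L, 9L))
  for (j in 1:9)
    expect_true(all(table(arr[, j]) == 9))
  for (i in 1:8) for (j in (i + 1):9) {
    tab <- table(arr[, i], arr[, j])
    expect_true(all(dim(tab) == c(3, 3)) && all(tab == 3),
                label = paste("columns", i, j, "orthogonal"))
  }
  # level mapping
  fd <- factor_definitions()
  lv <- lapply(1:9, function(j) unlist(fd[j, c("level1", "level2", "level3")]))
  mapped <- build_l27_array(levels = lv)
  for (j in 1:9) expect_true(all(mapped[, j] %in% lv[[j]]))
})

test_that("normalization is the exact affine map with exact inverse", {
  norm <- media_normalizer()
  # X1 spans (0.5, 2): endpoints and an interior point
  x <- c(0.5, 0, 0, 0.5, 0.5, 0.5, 0.5, 0.5, 0.5)
  expect_equal(unname(normalize_factors(x, norm)), rep(0, 9))
  hi <- c(2, 2, 2, 2.5, 2.5, 2, 2, 2, 2)
  expect_equal(unname(normalize_factors(hi, norm)), rep(1, 9))
  x[1] <- 1.76
  expect_equal(unname(normalize_factors(x, norm))[1], 0.84)
  # inverse round trip within 1e-12 on random points
  set.seed(41)
  Z <- matrix(runif(20 * 9), 20, 9)
  X <- denormalize_factors(Z, norm)
  expect_equal(normalize_factors(X, norm), Z, tolerance = 1e-12)
  # order preservation
  z <- normalize_factors(denormalize_factors(sort(runif(5))
                                             |> (\(v) cbind(v, matrix(0.5, 5, 8)))(),
                                             norm), norm)
  expect_true(all(diff(z[, 1]) > 0))
})

test_that("out-of-range inputs error unless clamping is requested", {
  dkw <- c(rep(1, 8), 0.1)
  expect_error(normalize_factors(dkw), "out")
  expect_warning(z <- normalize_factors(dkw, clamp = TRUE), "clamp")
  expect_equal(unname(z[9]), 0)
  expect_error(media_normalizer(cbind(rep(1, 9), rep(1, 9))))
})

test_that("design and metadata round-trip through their export formats", {
  csv <- tempfile(fileext = ".csv")
  write_design_csv("Rayen", csv)
  back <- read.csv(csv, stringsAsFactors = FALSE)
  d <- packaged_design("Rayen")
  expect_equal(back$PR_mean, d$PR_mean)
  expect_equal(back$X9, d$X9)
  js <- tempfile(fileext = ".json")
  write_factor_json(js)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(meta$code, paste0("X", 1:9))
  expect_equal(meta$level3, factor_definitions()$level3)
})
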