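test_that("cell diameter matches closed forms and a brute-force recomputation", {
  # all areas pi -> area-equivalent diameter 2
  tab <- random_cell_table(20, seed = 1)
  tab$area <- pi
  expect_equal(estimate_cell_diameter(tab), 2)

  # unit grid without areas -> median nearest-neighbor distance 1
  grid <- expand.grid(x = 0:4, y = 0:4)
  gt <- data.frame(sample_id = "s1", cell_id = sprintf("c%02d", 1:25),
                   x = grid$x, y = grid$y, M1 = 1,
                   cell_class = "cancer", stringsAsFactors = FALSE)
  expect_equal(estimate_cell_diameter(gt), 1)

  # random sample vs direct recomputation of the definition
  tab <- random_cell_table(150, seed = 2)
  lab <- tab$cell_class == "cancer"
  expect_equal(estimate_cell_diameter(tab, lab),
               median(2 * sqrt(tab$area[lab] / pi)))

  # single cancer cell without area is unusable
  one <- random_cell_table(10, seed = 3, cancer_frac = 0.1)
  one$area <- NULL
  expect_error(estimate_cell_diameter(one), "unusable")
})

test_that("neighborhoods include the boundary and exclude the index cell", {
  tab <- data.frame(sample_id = "s1", cell_id = c("a", "b", "c", "d"),
                    x = c(0, 3, 4, 10), y = 0, M1 = 1:4,
                    stringsAsFactors = FALSE)
  nb <- neighborhood(tab, "a", radius = 3)
  expect_identical(nb$cell_id, "b")   # exactly at radius: included
  nb <- neighborhood(tab, "a", radius = 4)
  expect_identical(nb$cell_id, c("b", "c"))
  expect_equal(nrow(neighborhood(tab, "d", radius = 5)), 0)
  expect_error(neighborhood(tab, "zz", radius = 1), "not found")
})

test_that("grid-indexed search equals the exhaustive oracle", {
  set.seed(4)
  n <- 1000
  x <- runif(n, 0, 60); y <- runif(n, 0, 60)
  qs <- sample.int(n, 50)
  for (radius in c(1.5, 5, 30)) {
    fast <- proxpress:::radius_search(x, y, radius, query = qs)
    for (k in seq_along(qs)) {
      expect_identical(fast[[k]], brute_neighbors(x, y, radius, qs[k]))
    }
  }
})

test_that("pressure follows the interpolated-percentile definition", {
  # one cancer cell at the origin, neighbors on a tight ring
  mk <- function(vals) {
    n <- length(vals)
    ang <- seq(0, 2 * pi, length.out = n + 1)[-1]
    data.frame(sample_id = "s1", cell_id = sprintf("c%02d", 0:n),
               x = c(0, 3 * cos(ang)), y = c(0, 3 * sin(ang)),
               area = c(pi * 25, rep(50, n)), M = c(0, vals),
               cell_class = c("cancer", rep("other", n)),
               stringsAsFactors = FALSE)
  }
  # singleton neighborhood -> the neighbor's value
  pp <- proximal_pressure(mk(7.5), markers = "M", radius_in_diameters = 1)
  expect_equal(pp$cells$pressure, 7.5)
  # {1..10} -> 9.1 under linear interpolation (nearest-rank would give 10)
  pp <- proximal_pressure(mk(1:10), markers = "M", radius_in_diameters = 1)
  expect_equal(pp$cells$pressure, 9.1)
  expect_equal(pp$samples$median_pressure, 9.1)
})

test_that("whole-pipeline pressures equal the exhaustive oracle", {
  for (seed in 1:4) {
    tab <- random_cell_table(400, n_markers = 2, seed = seed, field = 60)
    lab <- tab$cell_class == "cancer"
    pp <- proximal_pressure(tab, radius_in_diameters = 2, cancer_labels = lab)
    radius <- 2 * median(2 * sqrt(tab$area[lab] / pi))
    for (m in c("M1", "M2")) {
      want <- brute_pressure(tab, m, radius, which(lab))
      got <- pp$cells$pressure[pp$cells$marker == m]
      expect_equal(got, want, tolerance = 1e-9)
    }
  }
})

test_that("a field-covering radius reduces to the global percentile", {
  tab <- random_cell_table(300, seed = 9, field = 50)
  lab <- tab$cell_class == "cancer"
  pp <- proximal_pressure(tab, markers = "M1", radius_in_diameters = 1e6,
                          cancer_labels = lab)
  want <- vapply(which(lab), function(q) {
    brute_percentile(tab$M1[-q], 0.9)
  }, numeric(1))
  expect_equal(pp$cells$pressure, want, tolerance = 1e-9)
})

test_that("pressure is invariant under rigid motions and marker order", {
  tab <- random_cell_table(300, n_markers = 3, seed = 10, field = 80)
  lab <- tab$cell_class == "cancer"
  pp1 <- proximal_pressure(tab, cancer_labels = lab)

  th <- 0.71
  rot <- tab
  rot$x <- cos(th) * tab$x - sin(th) * tab$y + 123
  rot$y <- sin(th) * tab$x + cos(th) * tab$y - 45
  pp2 <- proximal_pressure(rot, cancer_labels = lab)
  expect_equal(pp2$cells$pressure, pp1$cells$pressure, tolerance = 1e-9)

  perm <- tab[, c("sample_id", "cell_id", "x", "y", "area",
                  "M3", "M1", "M2", "cell_class")]
  pp3 <- proximal_pressure(perm, cancer_labels = lab)
  for (m in c("M1", "M2", "M3")) {
    expect_equal(pp3$cells$pressure[pp3$cells$marker == m],
                 pp1$cells$pressure[pp1$cells$marker == m])
  }
})

test_that("raising a neighbor's value cannot lower any pressure", {
  tab <- random_cell_table(200, seed = 12, field = 50)
  lab <- tab$cell_class == "cancer"
  p1 <- proximal_pressure(tab, markers = "M1", cancer_labels = lab)
  set.seed(1)
  for (r in 1:5) {
    tab2 <- tab
    i <- sample(which(!lab), 1)
    tab2$M1[i] <- tab2$M1[i] + runif(1, 0.5, 10)
    p2 <- proximal_pressure(tab2, markers = "M1", cancer_labels = lab)
    expect_true(all(p2$cells$pressure >= p1$cells$pressure - 1e-12,
                    na.rm = TRUE))
  }
})

test_that("cohort z-scores have population mean 0 and variance 1", {
  cfg <- sim_config(n_samples_per_group = 3, n_cancer_cells = 60,
                    field_size = c(400, 400),
                    immune_populations = list(immune_population("CD8", 40, 1)),
                    seed = 31)
  co <- generate_cohort(cfg)
  pp <- proximal_pressure(normalize_markers(co$cells), markers = "CD8")
  z <- pp$samples$z
  expect_lt(abs(mean(z)), 1e-9)
  expect_lt(abs(mean(z^2) - 1), 1e-9)
})

test_that("per-patient collapse medians multi-core samples and rescores", {
  prof <- list(samples = data.frame(
    sample_id = sprintf("s%d", 1:6), marker = "CD8",
    n_cancer = 10L, n_empty = 0L,
    median_pressure = c(1, 3, 4, 8, 2, 6), z = NA_real_,
    stringsAsFactors = FALSE),
    params = list(markers = "CD8"))
  class(prof) <- "pressure_profile"
  meta <- data.frame(sample_id = sprintf("s%d", 1:6),
                     patient_id = c("p1", "p1", "p2", "p2", "p3", "p3"))
  pc <- collapse_by_patient(prof, meta)
  expect_equal(pc$median_pressure, c(2, 6, 4))  # per-patient medians
  expect_lt(abs(mean(pc$z)), 1e-12)
  expect_lt(abs(mean(pc$z^2) - 1), 1e-12)
})

test_that("group comparison matches the enumeration oracle and flags gaps", {
  prof <- list(samples = data.frame(
    sample_id = sprintf("s%d", 1:6),
    marker = "CD8", n_cancer = 10L, n_empty = 0L,
    median_pressure = c(1, 2, 3, 4, 5, 6), z = NA_real_,
    stringsAsFactors = FALSE),
    params = list(markers = "CD8"))
  class(prof) <- "pressure_profile"
  meta <- data.frame(sample_id = sprintf("s%d", 1:6),
                     response = rep(c("sensitive", "resistant"), each = 3))
  cmp <- compare_pressure(prof, meta)
  expect_equal(cmp$p_value, enumerate_ranksum_p(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(cmp$p_value, 0.1)
  expect_equal(cmp$direction, 1)

  # identical summaries in both groups: no discrimination
  prof$samples$median_pressure <- rep(c(1, 2, 3), 2)
  cmp <- compare_pressure(prof, meta)
  expect_equal(cmp$p_value, 1)
  expect_equal(cmp$direction, 0)

  # a group with no usable summaries is reported untestable
  prof$samples$median_pressure[meta$response == "resistant"] <- NA
  cmp <- compare_pressure(prof, meta)
  expect_true(cmp$untestable)
  expect_true(is.na(cmp$p_value))
})
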