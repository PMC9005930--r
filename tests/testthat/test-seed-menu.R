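menu_rasters <- function() {
  # 3x3 grid, hand-set probabilities for two species
  a <- matrix(c(0.73, 0.2, 0.4, 0.6, 0.5, 0.45, 0.9, 0.1, 0.3), 3, byrow = TRUE)
  b <- matrix(c(0.5, 0.35, 0.2, 0.4, 0.6, 0.8, 0.55, 0.65, 0.15), 3, byrow = TRUE)
  list(A = a, B = b)
}

test_that("point extraction reads the containing cell", {
  r <- menu_rasters()
  g <- grid_spec(3, 3)
  # cell (row 1, col 1) centre is (0.5, 2.5): value 0.73 for species A
  s <- site_set(coords = data.frame(site_id = "s1", x = 0.5, y = 2.5), grid = g)
  tab <- extract_at_sites(r, g, s)
  expect_equal(tab["A", "s1"], 0.73)
  expect_equal(tab["B", "s1"], 0.5)
})

test_that("polygon extraction applies the mean/min/max rule over covered cells", {
  vals <- matrix(c(0.2, 0.4, 0.6, 0, 0, 0, 0, 0, 0), 3, byrow = TRUE)
  g <- grid_spec(3, 3)
  # polygon covering the three top-row cell centres (y = 2.5)
  poly <- cbind(c(0.1, 2.9, 2.9, 0.1), c(2.1, 2.1, 2.9, 2.9))
  s <- site_set(polygons = list(p1 = poly), grid = g)
  expect_equal(extract_at_sites(list(sp = vals), g, s, "mean")["sp", "p1"], 0.4)
  expect_equal(extract_at_sites(list(sp = vals), g, s, "min")["sp", "p1"], 0.2)
  expect_equal(extract_at_sites(list(sp = vals), g, s, "max")["sp", "p1"], 0.6)
})

test_that("multipart polygons and out-of-grid sites are rejected", {
  g <- grid_spec(3, 3)
  ring <- cbind(c(0.1, 1, 1), c(0.1, 0.1, 1))
  expect_error(site_set(polygons = list(p = list(ring, ring)), grid = g), "multipart")
  expect_error(site_set(coords = data.frame(site_id = "s", x = 10, y = 1), grid = g),
               "outside")
  expect_error(site_set(), "no sites")
})

test_that("threshold rule includes at >= at ALL sites (AND rule)", {
  probs <- data.frame(s1 = c(0.5, 0.5), s2 = c(0.45, 0.35),
                      row.names = c("A", "B"))
  thr <- threshold_rule("fixed", c("A", "B"), fixed_value = 0.4)
  inc <- apply_threshold(probs, thr)
  expect_true(inc$included[inc$species_id == "A"])
  expect_false(inc$included[inc$species_id == "B"])
  # boundary: probability exactly at the threshold is included
  thr2 <- threshold_rule("fixed", c("A", "B"), fixed_value = 0.45)
  inc2 <- apply_threshold(probs, thr2)
  expect_true(inc2$included[inc2$species_id == "A"])
  # threshold 0 includes everything
  inc0 <- apply_threshold(probs, threshold_rule("fixed", c("A", "B"), fixed_value = 0))
  expect_true(all(inc0$included))
})

test_that("menu inclusion is monotone in thresholds and sites", {
  set.seed(33)
  probs3 <- data.frame(s1 = runif(6), s2 = runif(6), s3 = runif(6),
                       row.names = letters[1:6])
  sp <- rownames(probs3)
  for (t in c(0.2, 0.4, 0.6)) {
    lo <- apply_threshold(probs3, threshold_rule("fixed", sp, fixed_value = t))
    hi <- apply_threshold(probs3, threshold_rule("fixed", sp, fixed_value = t + 0.1))
    expect_true(all(sp[hi$included] %in% sp[lo$included]))  # raising removes only
    fewer <- apply_threshold(probs3[c("s1", "s2")],
                             threshold_rule("fixed", sp, fixed_value = t))
    expect_true(all(sp[lo$included] %in% sp[fewer$included]))  # adding a site removes only
  }
})

test_that("species-specific thresholds must be resolved", {
  probs <- data.frame(s1 = c(0.5, 0.6), row.names = c("A", "B"))
  expect_error(threshold_rule("max_sss", c("A", "B"),
                              species_thresholds = c(A = 0.3)), "unresolved")
  thr <- threshold_rule("max_sss", c("A", "B"),
                        species_thresholds = c(A = 0.55, B = 0.55))
  inc <- apply_threshold(probs, thr)
  expect_equal(inc$included, c(FALSE, TRUE))
  expect_error(threshold_rule("fixed", "A", fixed_value = 1.2), "\\[0, 1\\]")
})

test_that("menus join selected traits and flag missing species", {
  probs <- data.frame(s1 = c(0.9, 0.8, 0.2), row.names = c("A", "B", "C"))
  inc <- apply_threshold(probs, threshold_rule("fixed", c("A", "B", "C"), fixed_value = 0.5))
  traits <- make_trait_table(c("A", "B"), seed = 1)
  menu <- build_menu(inc, traits, c("growth_form", "lifespan", "pollinator_count"))
  expect_equal(nrow(menu), 2)
  expect_true(all(c("growth_form", "lifespan", "pollinator_count") %in% names(menu)))
  none <- build_menu(inc, traits, character(0))
  expect_false("growth_form" %in% names(none))
  expect_error(build_menu(inc, traits, "wingspan"), "available")
  # missing species keeps its row with NA traits and a warning
  traits_b <- traits[traits$species_id == "B", ]
  expect_warning(m2 <- build_menu(inc, traits_b), "missing")
  expect_equal(nrow(m2), 2)
  expect_true(anyNA(m2$growth_form))
  # CSV export writes a metadata header comment
  path <- withr::local_tempfile(fileext = ".csv")
  write_menu_csv(menu, path)
  expect_match(readLines(path, n = 1), "^# seed menu")
})

test_that("coverage map counts species above threshold, matching the menu engine", {
  r <- menu_rasters()
  g <- grid_spec(3, 3)
  thr <- threshold_rule("fixed", names(r), fixed_value = 0.5)
  cov <- coverage_map(r, thr)
  # oracle: apply the threshold at every cell treated as a site
  for (cell in 1:9) {
    xy <- cell_xy(g, cell)
    s <- site_set(coords = data.frame(site_id = "c", x = xy[1], y = xy[2]), grid = g)
    tab <- extract_at_sites(r, g, s)
    inc <- apply_threshold(tab, thr)
    expect_equal(cov[cell], sum(inc$included))
  }
  # degenerate thresholds
  expect_true(all(coverage_map(r, threshold_rule("fixed", names(r), fixed_value = 0)) == 2))
  thr_hi <- stats::setNames(rep(1.01, 2), names(r))  # impossible threshold
  expect_true(all(coverage_map(r, thr_hi) == 0))
})
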