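# Exact-rational region geometry and event support.

dd <- function(v, kappa = 1, events = numeric(0)) descriptor(v, kappa, events)

test_that("point costs follow d*C_D + l*C_L + c", {
  expect_equal(point_cost(c(0, 0, 0), 3, 4), 0)
  expect_equal(point_cost(c(1, 2, 3), 2, 1), 7)
  expect_equal(point_cost(c(1, 0, 0), 4.5, 1), 4.5)
})

test_that("a single count owns the whole box", {
  box <- cost_box("1/5", 5, "1/5", 5)
  regions <- compute_regions(list(dd(c(0, 0, 0))), box)
  expect_length(regions, 1L)
  expect_equal(regions[[1]]$dim, 2L)
  expect_equal(regions[[1]]$area, (5 - 0.2)^2)
  ver <- verify_landscape(regions, list(dd(c(0, 0, 0))), box)
  expect_true(ver$areas_sum_to_box)
  expect_true(ver$interiors_owned)
})

test_that("the known analytic boundary C_D = 2 C_L is reproduced exactly", {
  box <- cost_box("1/5", 5, "1/5", 5)
  front <- list(dd(c(1, 0, 0)), dd(c(0, 2, 0)))
  regions <- compute_regions(front, box)
  expect_length(regions, 2L)
  expect_true(all(vapply(regions, `[[`, 0L, "dim") == 2L))
  # the shared edge lies on C_D = 2 C_L: both regions contain the exact
  # boundary vertices (2/5, 1/5) and (5, 5/2)
  for (r in regions) {
    verts <- vapply(r$vertices, function(v)
      paste(dlcpareto:::rat_str(v$x), dlcpareto:::rat_str(v$y)), "")
    expect_true(all(c("2/5 1/5", "5 5/2") %in% verts))
  }
  ver <- verify_landscape(regions, front, box)
  expect_true(ver$areas_sum_to_box && ver$interiors_owned)
})

test_that("three counts partition the box with the derived boundaries", {
  # grid-argmin oracle at exact rational points fixes the expected owners
  box <- cost_box("1/5", 5, "1/5", 5)
  front <- list(dd(c(1, 0, 0)), dd(c(0, 1, 0)), dd(c(0, 0, 3)))
  regions <- compute_regions(front, box)
  expect_length(regions, 3L)
  keys <- vapply(regions, function(r) paste(r$v, collapse = ","), "")
  r3 <- regions[[match("0,0,3", keys)]]
  # <0,0,3> is optimal exactly on [3,5]x[3,5]
  verts <- vapply(r3$vertices, function(v)
    paste(dlcpareto:::rat_str(v$x), dlcpareto:::rat_str(v$y)), "")
  expect_setequal(verts, c("3 3", "5 3", "5 5", "3 5"))
  ver <- verify_landscape(regions, front, box)
  expect_true(ver$areas_sum_to_box && ver$interiors_owned)
  # dense-grid cross-check: the recorded owner minimizes at grid points
  for (cd in seq(0.25, 5, by = 0.75)) for (cl in seq(0.25, 5, by = 0.75)) {
    costs <- vapply(front, function(a) point_cost(a$v, cd, cl), 0)
    best <- min(costs)
    inside <- vapply(regions, function(r) {
      all(vapply(seq_along(front), function(j) {
        point_cost(r$v, cd, cl) <= point_cost(front[[j]]$v, cd, cl) + 1e-12
      }, TRUE))
    }, TRUE)
    expect_true(any(inside))
    for (i in which(inside))
      expect_equal(point_cost(regions[[i]]$v, cd, cl), best)
  }
})

test_that("degenerate (zero-area) regions are retained and classified", {
  box <- cost_box(1, 3, 1, 3)
  # <1,1,0> ties <2,0,0> and <0,2,0> exactly on lines; with symmetric
  # competitors it survives only on a segment or point
  front <- list(dd(c(2, 0, 0)), dd(c(0, 2, 0)), dd(c(1, 1, 0)))
  regions <- compute_regions(front, box)
  keys <- vapply(regions, function(r) paste(r$v, collapse = ","), "")
  expect_true("1,1,0" %in% keys)
  mid <- regions[[match("1,1,0", keys)]]
  expect_equal(mid$dim, 1L)       # the diagonal segment C_D = C_L
  expect_equal(mid$area, 0)
  ver <- verify_landscape(regions, front, box)
  expect_true(ver$areas_sum_to_box && ver$interiors_owned)
})

test_that("counts never minimal in the box are dropped", {
  box <- cost_box(1, 2, 1, 2)
  # <5,5,0> is everywhere beaten by <0,0,1> inside this box
  regions <- compute_regions(list(dd(c(0, 0, 1)), dd(c(5, 5, 0))), box)
  expect_length(regions, 1L)
  expect_equal(regions[[1]]$v, c(0L, 0L, 1L))
})

test_that("region and consensus support follow the definitions", {
  d1 <- dd(c(1, 0, 0), 2, c("dup|1|2" = 2, "spec|1|4" = 1))
  rs <- region_support(d1, 0)
  expect_equal(rs$support[rs$event == "dup|1|2"], 1)
  expect_equal(rs$support[rs$event == "spec|1|4"], 0.5)
  expect_equal(nrow(region_support(d1, 0.6)), 1L)
  d2 <- dd(c(0, 1, 0), 4, c("dup|1|2" = 1))
  expect_equal(nrow(region_support(d2, 0.5)), 0L)  # 1/4 < 0.5

  regs <- list(list(v = c(1, 0, 0), descriptor = d1, dim = 2L),
               list(v = c(0, 1, 0), descriptor = d2, dim = 1L),
               list(v = c(0, 0, 2), descriptor = dd(c(0, 0, 2), 1), dim = 2L))
  cs <- consensus_support(regs, 0)
  expect_equal(cs$support[cs$event == "dup|1|2"], 2 / 3)
  expect_equal(cs$support[cs$event == "spec|1|4"], 1 / 3)
  expect_equal(nrow(consensus_support(regs, 0.5)), 1L)
})

test_that("merged duplication identities give symmetric placements full support", {
  fr <- reconcile_landscape("(a1,a2);", "A;", c(a1 = "A", a2 = "A"))
  d <- fr$front[[1]]
  plain <- region_support(d, 0, merge_dups = FALSE)
  expect_equal(sort(plain$support[startsWith(plain$event, "dup|")]),
               c(0.5, 0.5))
  merged <- region_support(d, 0, merge_dups = TRUE)
  msup <- merged$support[startsWith(merged$event, "mdup|")]
  expect_equal(msup, 1)
  # the operation on the raw event set
  E <- merge_dup_identities(d$events)
  expect_false(any(startsWith(names(E), "dup|")))
  expect_true(any(startsWith(names(E), "mdup|")))
  expect_equal(merge_dup_identities(numeric(0)), numeric(0))
})

test_that("random fronts produce exact covering partitions", {
  set.seed(11)
  box <- cost_box("1/5", 5, "1/5", 5)
  for (rep in 1:25) {
    front <- pareto_subset(random_descriptor_set(5L))
    regions <- compute_regions(front, box)
    ver <- verify_landscape(regions, front, box, n_points = 200L)
    expect_true(ver$areas_sum_to_box)
    expect_true(ver$interiors_owned)
    # consistency: min over regions == min over the front at random points
    for (i in 1:20) {
      cd <- stats::runif(1, 0.2, 5); cl <- stats::runif(1, 0.2, 5)
      m_front <- min(vapply(front, function(a) point_cost(a$v, cd, cl), 0))
      m_reg <- min(vapply(regions, function(r) point_cost(r$v, cd, cl), 0))
      expect_equal(m_reg, m_front)
    }
  }
})
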