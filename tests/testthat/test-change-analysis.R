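make_bin <- function(v, species = "s", scenario = "current", lcc = TRUE) {
  b <- binarize(tiny_grid(v), 0.5, species = species, scenario_id = scenario)
  b$lcc_applied <- lcc
  b
}

test_that("change classification partitions cells exactly", {
  set.seed(1)
  cur_v <- matrix(rbinom(100, 1, 0.4), 10, 10)
  fut_v <- matrix(rbinom(100, 1, 0.4), 10, 10)
  cur <- make_bin(cur_v); fut <- make_bin(fut_v, scenario = "rcp85")
  ch <- classify_change(cur, fut)
  v <- ch$grid$values
  expect_equal(sum(v == 1) + sum(v == 2), sum(cur_v))       # loss+stable = current
  expect_equal(sum(v == 3) + sum(v == 2), sum(fut_v))       # gain+stable = future
  expect_equal(sum(v %in% 0:3), 100)                        # exact partition
  # identity scenario: no loss, no gain, stable = current
  ch_id <- classify_change(cur, cur)
  expect_equal(sum(ch_id$grid$values == 1), 0)
  expect_equal(sum(ch_id$grid$values == 3), 0)
  expect_equal(sum(ch_id$grid$values == 2), sum(cur_v))
  # future all-zero: loss = current
  ch0 <- classify_change(cur, make_bin(matrix(0, 10, 10)))
  expect_equal(sum(ch0$grid$values == 1), sum(cur_v))
  # flag and species mismatches error
  fut_nolcc <- make_bin(fut_v, lcc = FALSE)
  expect_error(classify_change(cur, fut_nolcc), "lcc_applied")
  expect_error(classify_change(cur, make_bin(fut_v, species = "other")),
               "different species")
  # no-dispersal variant empties the gain class
  ch_nd <- classify_change(cur, fut, dispersal = "none")
  expect_equal(sum(ch_nd$grid$values == 3), 0)
})

test_that("richness stacking counts species and commutes with masking", {
  set.seed(2)
  maps <- lapply(1:5, function(i)
    make_bin(matrix(rbinom(100, 1, 0.3), 10, 10), species = paste0("sp", i)))
  rich <- stack_richness(maps)
  expect_true(all(rich$values >= 0 & rich$values <= 5))
  # double-counting identity
  expect_equal(sum(rich$values),
               sum(vapply(maps, function(m) sum(m$grid$values), numeric(1))))
  # degenerate stack: identical maps give {0, n}
  same <- lapply(1:19, function(i) { m <- maps[[1]]; m$species <- paste0("s", i); m })
  expect_setequal(unique(as.vector(stack_richness(same)$values)), c(0, 19))
  # disjoint maps stay <= 1
  m1 <- matrix(0, 10, 10); m1[, 1:3] <- 1
  m2 <- matrix(0, 10, 10); m2[, 7:10] <- 1
  disj <- list(make_bin(m1, species = "a"), make_bin(m2, species = "b"))
  expect_lte(max(stack_richness(disj)$values), 1)
  expect_error(stack_richness(maps[c(1, 1)]), "duplicate species")
  # stack-then-mask equals mask-then-stack
  pam <- matrix(rbinom(100, 1, 0.5), 10, 10)
  masked_stack <- rich$values * pam
  maps_masked <- lapply(maps, function(m) {
    m$grid$values <- m$grid$values * pam; m
  })
  expect_equal(stack_richness(maps_masked)$values, masked_stack)
})

test_that("area by richness reports protected proportions with suppression", {
  rich1 <- tiny_grid(matrix(1, 10, 10))
  pa <- matrix(0, 10, 10); pa[1:5, 1:5] <- 1
  tab <- area_by_richness(rich1, tiny_grid(pa))
  expect_equal(tab$richness, 1)
  expect_equal(tab$area_km2, 100)
  expect_equal(tab$prop_protected, 0.25)
  # a level under 50 km^2 is suppressed
  rich2 <- tiny_grid(matrix(c(rep(1, 49), rep(2, 51)), 10, 10))
  tab2 <- area_by_richness(rich2, tiny_grid(pa))
  expect_true(is.na(tab2$prop_protected[tab2$richness == 1]))
  expect_false(is.na(tab2$prop_protected[tab2$richness == 2]))
  # level areas partition the suitable-anywhere area
  expect_equal(sum(tab2$area_km2), 100)
})

test_that("elevation profiles scale to a current-scenario maximum of one", {
  dem <- tiny_grid(matrix(rep(seq(25, 475, by = 50), each = 10), 10, 10))
  cur_v <- matrix(0, 10, 10); cur_v[, 3] <- 1    # all suitable cells in one bin
  bin <- make_bin(cur_v)
  prof <- elevation_profile(bin, dem)
  expect_equal(max(prof$scaled[, "current"]), 1)
  expect_equal(sum(prof$scaled[, "current"] > 0), 1)
  # future = current: stable profile equals current, loss/gain zero
  ch <- classify_change(bin, bin)
  prof_ch <- elevation_profile(ch, dem)
  expect_equal(prof_ch$scaled[, "stable"], prof_ch$scaled[, "current"])
  expect_true(all(prof_ch$scaled[, c("loss", "gain")] == 0))
  expect_equal(max(prof_ch$scaled[, "current"]), 1)
})

test_that("profile averaging keeps scale and demands shared bin edges", {
  dem <- tiny_grid(matrix(rep(seq(25, 475, by = 50), each = 10), 10, 10))
  one <- matrix(0, 10, 10); one[, 2] <- 1
  two <- matrix(0, 10, 10); two[, 8] <- 1
  p1 <- elevation_profile(make_bin(one, species = "a"), dem)
  p2 <- elevation_profile(make_bin(two, species = "b"), dem)
  avg <- average_profiles(list(p1, p2))
  expect_equal(max(avg$scaled[, "current"]), 0.5)   # disjoint peaks average to 0.5
  expect_equal(average_profiles(list(p1))$scaled, p1$scaled)
  p_short <- elevation_profile(make_bin(one), dem, n_bins = 3)
  expect_error(average_profiles(list(p1, p_short)), "inconsistent")
  # averaged current max is 1 iff species peak in the same bin
  p1b <- elevation_profile(make_bin(one, species = "c"), dem)
  expect_equal(max(average_profiles(list(p1, p1b))$scaled[, "current"]), 1)
})

test_that("an uphill-shifted future raises gain elevations above loss elevations", {
  # construct an elevation-tracking change directly: suitable band moves up
  dem <- tiny_grid(matrix(rep(seq(50, 950, length.out = 10), each = 10), 10, 10))
  cur_v <- matrix(0, 10, 10); cur_v[, 3:5] <- 1
  fut_v <- matrix(0, 10, 10); fut_v[, 5:7] <- 1
  ch <- classify_change(make_bin(cur_v), make_bin(fut_v, scenario = "rcp85"))
  expect_gt(mean_category_elevation(ch, dem, "gain"),
            mean_category_elevation(ch, dem, "loss"))
})
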