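wall_counts <- function(v) {
  c(smc = sum(v$occ == OCC[["SMC"]]), ecm = sum(v$occ == OCC[["ECM"]]),
    mp = sum(v$occ == OCC[["MP"]]), lumen = sum(v$occ == OCC[["lumen"]]),
    iel = sum(v$occ == OCC[["IEL"]]))
}

test_that("intimal add/remove shift one lumen site and conserve agents", {
  v <- tiny_section(seed = 1)
  before <- wall_counts(v)
  s <- which(v$layer == LAY[["intima"]])[10]
  v2 <- apply_intimal_change(v, s, "add", "SMC")
  after <- wall_counts(v2)
  expect_equal(after[["lumen"]], before[["lumen"]] - 1)
  expect_equal(after[["smc"]], before[["smc"]] + 1)
  expect_equal(after[["ecm"]], before[["ecm"]])
  expect_equal(after[["iel"]], before[["iel"]])
  # add followed by remove at the same site restores the lumen area
  v3 <- apply_intimal_change(v2, s, "remove")
  expect_equal(wall_counts(v3)[["lumen"]], before[["lumen"]])
  expect_error(apply_intimal_change(v, which(v$layer == LAY[["media"]])[1],
                                    "add"), "intima")
})

test_that("N random intimal adds reduce the lumen by exactly N", {
  v <- tiny_section(seed = 2)
  before <- wall_counts(v)
  set.seed(11)
  n <- 25
  for (k in seq_len(n)) {
    idx <- which(v$layer == LAY[["intima"]] & v$occ != OCC[["lumen"]])
    v <- apply_intimal_change(v, idx[sample.int(length(idx), 1)], "add",
                              sample(c("SMC", "ECM"), 1))
  }
  after <- wall_counts(v)
  expect_equal(after[["lumen"]], before[["lumen"]] - n)
  expect_equal(after[["smc"]] + after[["ecm"]],
               before[["smc"]] + before[["ecm"]] + n)
})

test_that("medial events never change the lumen area", {
  v <- tiny_section(seed = 3)
  before <- wall_counts(v)
  med_area <- sum(v$layer == LAY[["media"]])
  s <- which(v$layer == LAY[["media"]])[5]
  v2 <- apply_medial_change(v, s, "add", "ECM")
  expect_equal(wall_counts(v2)[["lumen"]], before[["lumen"]])
  expect_equal(sum(v2$layer == LAY[["media"]]), med_area + 1)
  # a balanced add/remove sequence leaves the media area unchanged
  set.seed(4)
  v3 <- v
  for (k in 1:10) {
    idx <- which(v3$layer == LAY[["media"]] & v3$occ != OCC[["exterior"]])
    v3 <- apply_medial_change(v3, idx[sample.int(length(idx), 1)], "add")
    idx <- which(v3$layer == LAY[["media"]] & v3$occ != OCC[["exterior"]])
    v3 <- apply_medial_change(v3, idx[sample.int(length(idx), 1)], "remove")
  }
  expect_equal(sum(v3$layer == LAY[["media"]]), med_area)
  expect_equal(wall_counts(v3)[["lumen"]], before[["lumen"]])
})

test_that("infiltration performs the three-site cyclic shift", {
  v <- tiny_section(seed = 5)
  before <- wall_counts(v)
  # a lumen-wall site: intima touching the lumen
  int <- which(v$layer == LAY[["intima"]])
  is_wall <- vapply(int, function(i) {
    nb <- v$geo$nb[i, ]; nb <- nb[nb > 0]
    any(v$occ[nb] == OCC[["lumen"]])
  }, logical(1))
  set.seed(6)
  v2 <- infiltration_rearrangement(v, int[is_wall][1])
  expect_true(attr(v2, "infiltrated"))
  after <- wall_counts(v2)
  expect_equal(after[["mp"]], before[["mp"]] + 1)
  expect_equal(after[["lumen"]], before[["lumen"]] - 1)
  expect_equal(after[["smc"]], before[["smc"]])
  expect_equal(after[["ecm"]], before[["ecm"]])
  # guarded no-op: a deep intima site has no empty lumen neighbour
  deep <- int[!is_wall][1]
  v3 <- infiltration_rearrangement(v, deep)
  expect_false(attr(v3, "infiltrated"))
  expect_identical(v3$occ, v$occ)
})

test_that("migration ledger: k migrations move k SMCs and fill with ECM", {
  v <- tiny_section(seed = 7)
  before <- section_areas(v)
  set.seed(8)
  k <- 5
  for (j in seq_len(k)) {
    src <- which(v$occ == OCC[["SMC"]] & v$layer == LAY[["media"]])[1]
    tgt <- which(v$layer == LAY[["intima"]] & v$occ != OCC[["lumen"]])[10]
    v <- migration_rearrangement(v, src, tgt)
  }
  after <- section_areas(v)
  expect_equal(after$media_smc, before$media_smc - k)
  expect_equal(after$media_ecm, before$media_ecm + k)
  expect_equal(after$intima_smc, before$intima_smc + k)
  expect_equal(after$lumen_area, before$lumen_area - k)
  # invalid source warns and leaves the section unchanged
  expect_warning(v4 <- migration_rearrangement(
    v, which(v$occ == OCC[["ECM"]] & v$layer == LAY[["media"]])[1],
    which(v$layer == LAY[["intima"]])[1]), "invalid")
  expect_identical(v4$occ, v$occ)
})

test_that("regularization is a fixed point on a smooth section", {
  v <- tiny_section(seed = 9)
  v2 <- regularize(v)
  expect_equal(attr(v2, "moves"), 0L)
  expect_identical(v2$occ, v$occ)
})

test_that("regularization relocates protrusions and preserves counts", {
  v <- tiny_section(seed = 10)
  # manufacture a one-site protrusion: put an agent on a lumen site that
  # touches the wall at a single point
  geo <- v$geo
  border <- which(v$occ == OCC[["lumen"]])
  contact <- vapply(border, function(i) {
    nb <- geo$nb[i, ]; nb <- nb[nb > 0]
    sum(v$occ[nb] %in% c(OCC[["SMC"]], OCC[["ECM"]], OCC[["MP"]],
                         OCC[["IEL"]]))
  }, numeric(1))
  spot <- border[which(contact == 1)[1]]
  v$occ[spot] <- OCC[["SMC"]]; v$clock[spot] <- 0
  v$layer[spot] <- LAY[["intima"]]
  before <- wall_counts(v)
  set.seed(2)
  v2 <- regularize(v)
  expect_gt(attr(v2, "moves"), 0L)
  after <- wall_counts(v2)
  expect_equal(after[c("smc", "ecm", "mp", "iel")],
               before[c("smc", "ecm", "mp", "iel")])
  # the spot itself is no longer occupied tissue with low contact
  expect_true(v2$occ[spot] == OCC[["lumen"]] ||
                sum(v2$occ[geo$nb[spot, ][geo$nb[spot, ] > 0]] %in%
                      c(1L, 2L, 3L, 4L)) > 1)
})

test_that("regularization reduces border roughness of a randomly roughened wall", {
  v <- tiny_section(seed = 12)
  set.seed(13)
  # random growth spurts make the border rough
  for (k in 1:20) {
    idx <- which(v$layer == LAY[["intima"]] & v$occ != OCC[["lumen"]])
    res <- cavsim:::shift_add(v, idx[sample.int(length(idx), 1)],
                              OCC[["ECM"]], OCC[["lumen"]], LAY[["intima"]])
    v <- res$section
  }
  perimeter <- function(v) {
    lum <- which(v$occ == OCC[["lumen"]])
    nb <- v$geo$nb[lum, , drop = FALSE]
    on <- nb > 0
    sum((nb > 0) & matrix(v$occ[pmax(nb, 1)] != OCC[["lumen"]], nrow(nb), 6) & on)
  }
  p0 <- perimeter(v)
  v2 <- regularize(v)
  expect_lte(perimeter(v2), p0)
  expect_equal(wall_counts(v2)[c("smc", "ecm", "mp")],
               wall_counts(v)[c("smc", "ecm", "mp")])
})

test_that("no agent crosses the IEL and gaps are refilled", {
  v <- tiny_section(seed = 14)
  # simulate an IEL gap
  gap <- v$iel_ring[1]
  v$occ[gap] <- OCC[["ECM"]]
  v2 <- regularize(v)
  expect_equal(v2$occ[gap], OCC[["IEL"]])
  # intimal adds never disturb the IEL ring
  set.seed(15)
  v3 <- tiny_section(seed = 14)
  for (k in 1:30) {
    idx <- which(v3$layer == LAY[["intima"]] & v3$occ != OCC[["lumen"]])
    v3 <- apply_intimal_change(v3, idx[sample.int(length(idx), 1)], "add")
  }
  expect_true(all(v3$occ[v3$iel_ring] == OCC[["IEL"]]))
})
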