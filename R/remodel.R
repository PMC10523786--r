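# Lattice rearrangements: inward intimal growth/shrinkage, outward medial
# growth/shrinkage, macrophage infiltration, SMC migration and border/IEL
# regularization.
#
# Growth is realized as a discrete ray shift: the 6-neighbour chain from the
# event site to its nearest lumen (intimal events) or exterior (medial
# events) site.  The nearest-border ray keeps growth locally perpendicular
# to the border and is guaranteed to terminate even for concave lumens.

# Nearest site with occupancy `code`, found by an expanding local box
# search around `from` (avoids scanning the whole lattice per event).
nearest_with_occ <- function(v, from, code, w0 = 8L) {
  geo <- v$geo
  r <- geo$row[from]; c <- geo$col[from]
  w <- w0
  repeat {
    rows <- max(1L, r - w):min(geo$nr, r + w)
    cols <- max(1L, c - w):min(geo$nc, c + w)
    idx <- rep(rows, length(cols)) +
      rep((cols - 1L) * geo$nr, each = length(rows))
    hit <- idx[v$occ[idx] == code]
    if (length(hit) > 0L) {
      d2 <- (geo$x[hit] - geo$x[from])^2 + (geo$y[hit] - geo$y[from])^2
      # accept only if the true disc of radius w was fully covered, so the
      # nearest box hit is the nearest site overall
      if (min(d2) <= (w - 1)^2 || (length(rows) == geo$nr &&
                                   length(cols) == geo$nc))
        return(hit[which.min(d2)])
    }
    if (length(rows) == geo$nr && length(cols) == geo$nc) return(NA_integer_)
    w <- w * 2L
  }
}

# Pick the border site where a shifted column meets the empty phase.  The
# natural exit is the nearest empty site, but agents are locally
# redistributed to keep the border smooth: within a window along the border,
# additions deposit where the border lags behind (for the inner border, the
# lumen site farthest from the centre; for the outer border, the exterior
# site closest in) and removals take tissue from where it runs ahead.
# Contact maximization breaks ties, so kinks still get rounded off.
choose_exit <- function(v, from, stop_occ, action, window = 9) {
  t0 <- nearest_with_occ(v, from, stop_occ)
  if (is.na(t0)) return(NA_integer_)
  geo <- v$geo
  w <- as.integer(ceiling(window / (sqrt(3) / 2)))
  rows <- max(1L, geo$row[t0] - w):min(geo$nr, geo$row[t0] + w)
  cols <- max(1L, geo$col[t0] - w):min(geo$nc, geo$col[t0] + w)
  box <- rep(rows, length(cols)) +
    rep((cols - 1L) * geo$nr, each = length(rows))
  cand <- box[v$occ[box] == stop_occ]
  d <- sqrt((geo$x[cand] - geo$x[t0])^2 + (geo$y[cand] - geo$y[t0])^2)
  cand <- cand[d <= window]
  cc <- tissue_contact(v, cand)
  cand <- cand[cc > 0L]; cc <- cc[cc > 0L]   # border sites only
  if (length(cand) == 0L) return(t0)
  # border height: distance from the cross-section centre
  dc <- geo$dc[cand]
  # inner border (lumen exits): under-grown spots have large dc; outer
  # border (exterior exits): under-grown spots have small dc
  height <- if (stop_occ == .LUMEN) dc else -dc
  score <- if (action == "add") height else -height
  # quantize the height so contact still decides among near-level spots
  score <- round(score * 2) / 2 + cc / 10 * (if (action == "add") 1 else -1)
  best <- which(score == max(score))
  if (length(best) > 1L) {
    dd <- (geo$x[cand[best]] - geo$x[from])^2 +
      (geo$y[cand[best]] - geo$y[from])^2
    best <- best[which.min(dd)]
  }
  cand[best[1L]]
}

# Chain of linear indices from `from` to the first site whose occupancy is
# `stop_occ`, stepping to the neighbour closest to the exit site (ties
# broken by neighbour order).  Returns NULL if the walk strays into a
# forbidden occupancy or exceeds the step bound.
ray_chain <- function(v, from, stop_occ, forbidden, max_steps = 400L,
                      action = "add") {
  geo <- v$geo
  target <- choose_exit(v, from, stop_occ, action)
  if (is.na(target)) return(NULL)
  tx <- geo$x[target]; ty <- geo$y[target]
  chain <- integer(max_steps)
  chain[1L] <- from
  cur <- from
  occ <- v$occ
  for (k in 2:max_steps) {
    nb <- geo$nb[cur, ]
    nb <- nb[nb > 0L]
    dd <- (geo$x[nb] - tx)^2 + (geo$y[nb] - ty)^2
    nxt <- nb[which.min(dd)]
    o <- occ[nxt]
    if (o == forbidden) return(NULL)
    chain[k] <- nxt
    if (o == stop_occ) return(chain[seq_len(k)])
    cur <- nxt
  }
  NULL
}

# internal kernel shared by the intimal/medial ops; returns the updated
# section plus the content displacement map (from -> to), or NULL on abort
shift_add <- function(v, site, payload, stop_occ, new_layer) {
  chain <- ray_chain(v, site, stop_occ, forbidden = .IEL, action = "add")
  if (is.null(chain)) return(NULL)
  k <- length(chain)
  # contents move one step outward along the chain towards the border site
  v$occ[chain[2:k]] <- v$occ[chain[1:(k - 1L)]]
  v$clock[chain[2:k]] <- v$clock[chain[1:(k - 1L)]]
  v$occ[chain[1L]] <- payload
  v$clock[chain[1L]] <- 0
  v$layer[chain[k]] <- new_layer   # border site converted to tissue
  list(section = v, moved_from = chain[1:(k - 1L)], moved_to = chain[2:k])
}

shift_remove <- function(v, site, stop_occ, freed_layer) {
  chain <- ray_chain(v, site, stop_occ, forbidden = .IEL, action = "remove")
  if (is.null(chain)) return(NULL)
  k <- length(chain)
  if (k == 2L) {
    v$occ[site] <- if (stop_occ == .LUMEN) .LUMEN else .EXT
    v$clock[site] <- NA_real_
    v$layer[site] <- freed_layer
    return(list(section = v, moved_from = integer(0), moved_to = integer(0)))
  }
  # contents between the site and the border shift back to fill the void
  v$occ[chain[1:(k - 2L)]] <- v$occ[chain[2:(k - 1L)]]
  v$clock[chain[1:(k - 2L)]] <- v$clock[chain[2:(k - 1L)]]
  freed <- chain[k - 1L]
  v$occ[freed] <- if (stop_occ == .LUMEN) .LUMEN else .EXT
  v$clock[freed] <- NA_real_
  v$layer[freed] <- freed_layer
  list(section = v, moved_from = chain[2:(k - 1L)], moved_to = chain[1:(k - 2L)])
}

#' Apply an intimal growth or shrinkage event
#'
#' Intimal events remodel inward: an `"add"` shifts the tissue between the
#' event site and the lumen one site inward, converts the reached lumen site
#' to intima and places the new agent at the event site (lumen area -1);
#' a `"remove"` deletes the agent and shifts the same tissue outward,
#' freeing one lumen site (+1).
#'
#' @param v A [vessel_section].
#' @param site Event site (linear index or `(row, col)`), must be intimal.
#' @param action `"add"` or `"remove"`.
#' @param payload Occupant placed on `"add"`: `"SMC"`, `"ECM"` or `"MP"`.
#' @return The remodeled `vessel_section`.
#' @export
apply_intimal_change <- function(v, site, action = c("add", "remove"),
                                 payload = "SMC") {
  action <- match.arg(action)
  site <- site_index(v$geo, site)
  if (v$layer[site] != .LY_INT)
    stop("intimal change requested outside the intima", call. = FALSE)
  res <- if (action == "add") {
    shift_add(v, site, occ_code(payload), .LUMEN, .LY_INT)
  } else {
    shift_remove(v, site, .LUMEN, .LY_LUMEN)
  }
  if (is.null(res))
    stop("no lumen reachable from the event site (occluded ray)",
         call. = FALSE)
  res$section
}

#' Apply a medial growth or shrinkage event
#'
#' Medial events remodel outward: the exterior boundary advances or retreats
#' by one site and the lumen area is unchanged.
#'
#' @inheritParams apply_intimal_change
#' @export
apply_medial_change <- function(v, site, action = c("add", "remove"),
                                payload = "SMC") {
  action <- match.arg(action)
  site <- site_index(v$geo, site)
  if (v$layer[site] != .LY_MED)
    stop("medial change requested outside the media", call. = FALSE)
  res <- if (action == "add") {
    shift_add(v, site, occ_code(payload), .EXT, .LY_MED)
  } else {
    shift_remove(v, site, .EXT, .LY_EXT)
  }
  if (is.null(res))
    stop("media ring broken: no exterior reachable", call. = FALSE)
  res$section
}

occ_code <- function(payload) {
  code <- match(payload, .OCC_LEVELS) - 1L
  if (is.na(code) || !(code %in% c(.SMC, .ECM, .MP)))
    stop("payload must be one of 'SMC', 'ECM', 'MP'", call. = FALSE)
  code
}

#' Macrophage infiltration rearrangement
#'
#' Three-site cyclic shift at the access site `i`: the content of `i` moves
#' into a random empty (lumen) neighbour `e`, the agent of a random deeper
#' intimal neighbour `d` moves into `i`, and `d` receives the new macrophage.
#' Net effect: one more intimal macrophage, lumen area -1.  When no valid
#' `e` or `d` exists the infiltration is aborted and the section returned
#' unchanged.
#'
#' @param v A [vessel_section].
#' @param access_site Lumen-wall site (linear index or `(row, col)`).
#' @return The remodeled `vessel_section`; attribute `"infiltrated"` reports
#'   whether the rearrangement happened.
#' @export
infiltration_rearrangement <- function(v, access_site) {
  i <- site_index(v$geo, access_site)
  nb <- v$geo$nb[i, ]
  nb <- nb[nb > 0L]
  e_pool <- nb[v$occ[nb] == .LUMEN]
  d_pool <- nb[v$layer[nb] == .LY_INT & v$occ[nb] != .LUMEN &
                 v$geo$dc[nb] > v$geo$dc[i]]
  if (length(e_pool) == 0L || length(d_pool) == 0L) {
    attr(v, "infiltrated") <- FALSE
    return(v)
  }
  e <- e_pool[sample.int(length(e_pool), 1L)]
  d <- d_pool[sample.int(length(d_pool), 1L)]
  v$occ[e] <- v$occ[i]; v$clock[e] <- v$clock[i]
  v$layer[e] <- .LY_INT
  v$occ[i] <- v$occ[d]; v$clock[i] <- v$clock[d]
  v$occ[d] <- .MP; v$clock[d] <- 0
  attr(v, "infiltrated") <- TRUE
  attr(v, "map") <- list(from = c(i, d), to = c(e, i))
  v
}

#' SMC media-to-intima migration rearrangement
#'
#' The medial SMC relocates to the intimal target through an inward-oriented
#' intimal add (lumen area -1), and a new ECM agent fills the vacated medial
#' site, so the media progressively trades SMC content for ECM.
#'
#' @param v A [vessel_section].
#' @param source Medial SMC site.
#' @param target Intimal end-site.
#' @return The remodeled `vessel_section`.
#' @export
migration_rearrangement <- function(v, source, target) {
  source <- site_index(v$geo, source)
  target <- site_index(v$geo, target)
  if (v$occ[source] != .SMC || v$layer[source] != .LY_MED ||
      v$layer[target] != .LY_INT) {
    warning("invalid migration source/target; section unchanged")
    return(v)
  }
  v2 <- apply_intimal_change(v, target, "add", payload = "SMC")
  v2$clock[target] <- v$clock[source]   # the migrating cell keeps its clock
  v2$occ[source] <- .ECM
  v2$clock[source] <- 0
  v2
}

# wall-tissue contact count (SMC/ECM/MP/IEL neighbours) for given sites
tissue_contact <- function(v, idx) {
  if (length(idx) == 0L) return(integer(0))
  nb <- v$geo$nb[idx, , drop = FALSE]
  cnt <- matrix(0L, nrow(nb), 6L)
  on <- nb > 0L
  cnt[on] <- as.integer(v$occ[nb[on]] %in% c(.SMC, .ECM, .MP, .IEL))
  as.integer(rowSums(cnt))
}

#' Regularize the cross-section borders
#'
#' Locally redistributes border agents to maximize tissue contact, keeping
#' the lumen and outer profiles smooth: border sites with fewer than three
#' same-tissue neighbours are relocated to a nearby border position with
#' strictly higher contact, iterating up to `max_passes` passes.  Agent
#' counts of every type are preserved, no agent crosses the IEL, and any IEL
#' site whose inert agent was lost is refilled at its original ring position.
#'
#' @param v A [vessel_section].
#' @param max_passes Upper bound on smoothing passes per call.
#' @param reach How far (sites) a protruding agent may be relocated.
#' @return The regularized `vessel_section`; attribute `"moves"` counts the
#'   relocations performed.
#' @export
regularize <- function(v, max_passes = 5L, reach = 5) {
  geo <- v$geo
  moves <- 0L
  for (pass in seq_len(max_passes)) {
    cells <- v$occ == .SMC | v$occ == .ECM | v$occ == .MP
    # inner border: intimal tissue poking into the lumen
    moved <- regularize_side(v, geo, .LY_INT, .LUMEN, .LY_LUMEN, reach, cells)
    v <- moved$section; n1 <- moved$n
    # outer border: medial tissue poking into the exterior
    moved <- regularize_side(v, geo, .LY_MED, .EXT, .LY_EXT, reach, cells)
    v <- moved$section; n2 <- moved$n
    moves <- moves + n1 + n2
    if (n1 + n2 == 0L) break
  }
  # IEL ring restoration
  gap <- v$iel_ring[v$occ[v$iel_ring] != .IEL]
  if (length(gap) > 0L) {
    v$occ[gap] <- .IEL
    v$clock[gap] <- NA_real_
  }
  attr(v, "moves") <- moves
  v
}

# one smoothing pass on one side; empty_occ is the phase the border touches
regularize_side <- function(v, geo, tissue_layer, empty_occ, empty_layer,
                            reach, cells = NULL) {
  if (is.null(cells)) cells <- v$occ == .SMC | v$occ == .ECM | v$occ == .MP
  tis <- which(cells & v$layer == tissue_layer)
  if (length(tis) == 0L) return(list(section = v, n = 0L))
  nb <- geo$nb[tis, , drop = FALSE]
  on <- nb > 0L
  touch <- matrix(FALSE, nrow(nb), 6L)
  touch[on] <- v$occ[nb[on]] == empty_occ
  border <- tis[rowSums(touch) > 0L]
  if (length(border) == 0L) return(list(section = v, n = 0L))
  contact <- tissue_contact(v, border)
  prot <- border[contact <= 2L]
  if (length(prot) == 0L) return(list(section = v, n = 0L))
  prot <- prot[sample.int(length(prot))]
  n_moved <- 0L
  for (p in prot) {
    cp <- tissue_contact(v, p)
    if (cp > 2L) next   # may have been fixed by an earlier move
    # candidate destinations: empty sites near p (local box search)
    w <- as.integer(ceiling(reach / (sqrt(3) / 2)))
    rows <- max(1L, geo$row[p] - w):min(geo$nr, geo$row[p] + w)
    cols <- max(1L, geo$col[p] - w):min(geo$nc, geo$col[p] + w)
    box <- rep(rows, length(cols)) +
      rep((cols - 1L) * geo$nr, each = length(rows))
    cand <- box[v$occ[box] == empty_occ]
    if (length(cand) == 0L) next
    d <- sqrt((geo$x[cand] - geo$x[p])^2 + (geo$y[cand] - geo$y[p])^2)
    cand <- cand[d <= reach & cand != p]
    if (length(cand) == 0L) next
    cc <- tissue_contact(v, cand)
    best <- which(cc == max(cc))
    if (length(best) > 1L) {
      dd <- sqrt((geo$x[cand[best]] - geo$x[p])^2 +
                   (geo$y[cand[best]] - geo$y[p])^2)
      best <- best[which.min(dd)]
    }
    dest <- cand[best]
    if (tissue_contact(v, dest) <= cp + 1L) next  # require a strict gain
    v$occ[dest] <- v$occ[p]; v$clock[dest] <- v$clock[p]
    v$layer[dest] <- tissue_layer
    v$occ[p] <- empty_occ; v$clock[p] <- NA_real_
    v$layer[p] <- empty_layer
    n_moved <- n_moved + 1L
  }
  list(section = v, n = n_moved)
}
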