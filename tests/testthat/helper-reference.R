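# Plain R reference interpreter for the 1D loop-extrusion rules.
#
# Applies the update rules one by one with no optimization, drawing from R's
# RNG with exactly the same draw protocol as the compiled engine, so that
# under the same seed both produce identical state sequences.

ref_floor_unif <- function(k) min(floor(runif(1) * k), k - 1)

ref_extrusion <- function(spec, params, sample_every = 1L,
                          max_tries = 1000L) {
  n <- spec$n_nucleosomes
  centro <- rep(FALSE, n)
  centro[spec$centromere_positions + 1L] <- TRUE
  barrier <- params$mode %in% c("blocking", "anchoring")
  anchoring <- params$mode == "anchoring"
  p_unbind <- 1 / params$lifetime
  n_les <- params$n_les

  occ <- rep(FALSE, n)
  L <- integer(n_les); R <- integer(n_les)
  pair_free <- function(i) {
    !occ[i + 1L] && !occ[i + 2L] &&
      !(barrier && (centro[i + 1L] || centro[i + 2L]))
  }
  if (!is.null(params$seed)) set.seed(params$seed)
  for (k in seq_len(n_les)) {
    placed <- FALSE
    for (t in seq_len(max_tries * 10L)) {
      i <- ref_floor_unif(n - 1L)
      if (pair_free(i)) {
        L[k] <- i; R[k] <- i + 1L
        occ[i + 1L] <- occ[i + 2L] <- TRUE
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("reference: could not place LE")
  }

  states <- list(list(step = 0L, left = L, right = R))
  for (step in seq_len(params$n_steps)) {
    perm <- seq_len(n_les)
    if (n_les > 1L) {
      for (i in seq(n_les, 2L)) {
        j <- ref_floor_unif(i) + 1L
        tmp <- perm[i]; perm[i] <- perm[j]; perm[j] <- tmp
      }
    }
    for (k in perm) {
      d <- L[k] - 1L
      if (d >= 0L && !occ[d + 1L] && !(barrier && centro[d + 1L])) {
        occ[L[k] + 1L] <- FALSE; occ[d + 1L] <- TRUE; L[k] <- d
      }
      d <- R[k] + 1L
      if (d < n && !occ[d + 1L] && !(barrier && centro[d + 1L])) {
        occ[R[k] + 1L] <- FALSE; occ[d + 1L] <- TRUE; R[k] <- d
      }
      anchored <- anchoring &&
        ((L[k] > 0L && centro[L[k]]) || (R[k] < n - 1L && centro[R[k] + 2L]))
      if (!anchored && runif(1) < p_unbind) {
        oldL <- L[k]; oldR <- R[k]
        occ[oldL + 1L] <- occ[oldR + 1L] <- FALSE
        placed <- FALSE
        for (t in seq_len(max_tries)) {
          i <- ref_floor_unif(n - 1L)
          if (pair_free(i)) {
            L[k] <- i; R[k] <- i + 1L
            occ[i + 1L] <- occ[i + 2L] <- TRUE
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          L[k] <- oldL; R[k] <- oldR
          occ[oldL + 1L] <- occ[oldR + 1L] <- TRUE
        }
      }
    }
    if (step %% sample_every == 0L || step == params$n_steps) {
      states[[length(states) + 1L]] <- list(step = step, left = L, right = R)
    }
  }
  states
}

# O(k^2) brute-force axial-nucleosome oracle: a leg is axial iff it is not
# strictly inside any other LE's open interval.
brute_axial <- function(left, right) {
  legs <- c(left, right)
  keep <- vapply(legs, function(p) {
    !any(left < p & p < right)
  }, logical(1))
  sort(legs[keep])
}

# brute-force contact map on one frame
brute_contact_map <- function(coords, from, to, bin_sites, radius) {
  idx <- from:to
  n_bins <- ceiling(length(idx) / bin_sites)
  M <- matrix(0, n_bins, n_bins)
  for (a in seq_along(idx)) {
    for (b in seq(a, length(idx))) {
      d <- sqrt(sum((coords[idx[a] + 1L, ] - coords[idx[b] + 1L, ])^2))
      if (d <= radius) {
        ba <- (a - 1L) %/% bin_sites + 1L
        bb <- (b - 1L) %/% bin_sites + 1L
        M[ba, bb] <- M[ba, bb] + 1
        if (ba != bb) M[bb, ba] <- M[bb, ba] + 1
      }
    }
  }
  M
}

# brute-force contact probability on one frame (separations in sites)
brute_contact_probability <- function(coords, radius, breaks_sites) {
  n <- nrow(coords)
  nb <- length(breaks_sites) - 1L
  contacts <- numeric(nb); possible <- numeric(nb)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      s <- j - i
      if (s < breaks_sites[1] || s >= breaks_sites[nb + 1L]) next
      b <- findInterval(s, breaks_sites)
      possible[b] <- possible[b] + 1
      d <- sqrt(sum((coords[i, ] - coords[j, ])^2))
      if (d <= radius) contacts[b] <- contacts[b] + 1
    }
  }
  list(contacts = contacts, possible = possible)
}

# convert reference interpreter output to matrices comparable to a bond_trace
ref_states_matrix <- function(states, field) {
  do.call(rbind, lapply(states, `[[`, field))
}
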