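# Shared fixtures and independent oracles. Oracles deliberately re-derive
# results from first principles and never call the code paths they check.

# minimal valid observation rows ------------------------------------------

control_obs <- function(plate = 1L, group = "WT_CONTROL", distances = 1,
                        column = if (group == "WT_CONTROL") 1L else 12L) {
  n <- length(distances)
  data.frame(plate = plate, row = LETTERS[seq_len(n)], column = column,
             fish_index = 1L, group = group, drug_id = NA_character_,
             alive = TRUE, distance_m = distances,
             stringsAsFactors = FALSE)
}

treated_obs <- function(drug_id, distances, alive = rep(TRUE,
                        length(distances)), plate = 1L, row = "A",
                        column = 2L) {
  data.frame(plate = plate, row = row, column = column,
             fish_index = seq_along(distances), group = "TREATED",
             drug_id = drug_id, alive = alive,
             distance_m = ifelse(alive, distances, 0),
             stringsAsFactors = FALSE)
}

# one-plate toy screen: WT controls around 1 m, MO controls near 0
toy_screen <- function(treated = NULL, wt = c(0.9, 1.0, 1.1, 1.0),
                       mo = c(0, 0, 0.15, 0)) {
  obs <- rbind(control_obs(group = "WT_CONTROL", distances = wt),
               control_obs(group = "MO_CONTROL", distances = mo))
  if (!is.null(treated)) obs <- rbind(obs, treated)
  screen_table(obs)
}

# independent re-statement of the four-way classification rules ------------

oracle_classify <- function(z, alive, mean_thr = 0, fish_thr = -1,
                            dead_min = 3, hit_min = 2) {
  if (sum(!alive) >= dead_min) return("TOXIC")
  za <- z[alive]
  if (sum(za > fish_thr) < hit_min) return("NON_HIT")
  if (mean(za) > mean_thr) "HIT_A" else "HIT_B"
}

# brute-force Holm step-down from the definition --------------------------

oracle_holm <- function(p) {
  m <- length(p)
  out <- numeric(m)
  for (i in seq_len(m)) {
    # adjusted p_i = max over all j with p_j <= p_i of min(1, (m-rank+1)p_j)
    o <- order(p)
    r <- which(o == i)  # rank of p_i
    vals <- vapply(seq_len(r), function(j) min(1, (m - j + 1) * p[o[j]]),
                   numeric(1))
    out[i] <- max(vals)
  }
  out
}

# union-find connected components oracle -----------------------------------

oracle_components <- function(nodes, edges_a, edges_b) {
  parent <- setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  roots <- vapply(nodes, find, character(1))
  match(roots, unique(roots))
}

# brute-force binary erosion oracle ----------------------------------------

oracle_erode <- function(mask, r, disk = TRUE) {
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(FALSE, h, w)
  for (i in seq_len(h)) for (j in seq_len(w)) {
    if (!mask[i, j]) next
    keep <- TRUE
    for (di in -r:r) for (dj in -r:r) {
      if (disk && di^2 + dj^2 > r^2) next
      qi <- i + di; qj <- j + dj
      if (qi < 1 || qi > h || qj < 1 || qj > w || !mask[qi, qj]) {
        keep <- FALSE
      }
    }
    out[i, j] <- keep
  }
  out
}

# brute-force 3x3 local maxima of a component ------------------------------

oracle_local_maxima <- function(channel, comp_mask) {
  h <- nrow(channel); w <- ncol(channel)
  idx <- which(comp_mask, arr.ind = TRUE)
  keep <- logical(nrow(idx))
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    ni <- max(1, i - 1):min(h, i + 1)
    nj <- max(1, j - 1):min(w, j + 1)
    keep[r] <- channel[i, j] >= max(channel[ni, nj])
  }
  idx[keep, , drop = FALSE]
}

# simple binary mask with a rendered straight axon --------------------------

straight_axon_mask <- function(h = 200, w = 100, length_px = 120,
                               row0 = 40, col = 50) {
  pts <- cbind(seq(row0, row0 + length_px, length.out = 31), rep(col, 31))
  nmjscreen:::render_polyline(matrix(0, h, w), pts, width = 3,
                              intensity = 1) > 0
}
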