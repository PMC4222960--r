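# Independent brute-force oracles, kept deliberately naive: per-pixel loops
# and direct summation, no shared code with the package internals.

oracle_offsets <- function(diameter) {
  r <- diameter / 2
  b <- floor(r)
  out <- NULL
  for (dx in -b:b) for (dy in -b:b)
    if (dx^2 + dy^2 <= r^2) out <- rbind(out, c(dx, dy))
  out
}

# window statistic at every pixel by explicit enumeration; mask restricts to
# flagged pixels (no growth fallback: callers pick masks dense enough)
oracle_window_stat <- function(img, diameter, stat = c("mean", "sd", "median"),
                               mask = NULL) {
  stat <- match.arg(stat)
  off <- oracle_offsets(diameter)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    ii <- i + off[, 1]; jj <- j + off[, 2]
    ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
    idx <- cbind(ii[ok], jj[ok])
    if (!is.null(mask)) idx <- idx[mask[idx], , drop = FALSE]
    v <- img[idx]
    out[i, j] <- switch(stat,
      mean = mean(v),
      sd = sqrt(mean((v - mean(v))^2)),
      median = median(v))
  }
  out
}

# direct-summation coefficient oracles over a selection
oracle_r <- function(R, G, sel) {
  x <- R[sel]; y <- G[sel]
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

oracle_h <- function(R, G, sel) {
  x <- R[sel]; y <- G[sel]
  length(x) * sum(x * y) / (sum(x) * sum(y))
}

oracle_moc <- function(R, G, sel) {
  x <- R[sel]; y <- G[sel]
  sum(x * y) / sqrt(sum(x^2) * sum(y^2))
}

oracle_m12 <- function(R, G, fg1, fg2) {
  c(sum(R[fg1 & fg2]) / sum(R[fg1]), sum(G[fg1 & fg2]) / sum(G[fg2]))
}

# brute-force region decomposition: edge = background pixels 8-adjacent to
# foreground, annuli by explicit minimum distance to edge-pixel centres
oracle_regions <- function(fg, width) {
  nr <- nrow(fg); nc <- ncol(fg)
  edge <- NULL
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (fg[i, j]) next
    nb <- FALSE
    for (di in -1:1) for (dj in -1:1) {
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && fg[ii, jj]) nb <- TRUE
    }
    if (nb) edge <- rbind(edge, c(i, j))
  }
  ann <- matrix(FALSE, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    d2 <- min((edge[, 1] - i)^2 + (edge[, 2] - j)^2)
    ann[i, j] <- d2 <= width^2
  }
  list(inner = fg & ann, centre = fg & !ann,
       outer = !fg & ann, remainder = !fg & !ann)
}

random_test_image <- function(nr, nc, max_val = 255) {
  matrix(sample(0:max_val, nr * nc, replace = TRUE), nr, nc)
}
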