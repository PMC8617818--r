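## Independent brute-force oracles. These deliberately re-derive results
## pixel by pixel / element by element, sharing no code with the package
## implementation.

## Disc offsets derived independently of the package helper.
oracle_disc <- function(r) {
  out <- list()
  for (dy in -r:r) for (dx in -r:r)
    if (dy * dy + dx * dx <= r * r) out[[length(out) + 1]] <- c(dy, dx)
  do.call(rbind, out)
}

## Minkowski sum of two offset sets (the composed structuring element).
compose_offsets <- function(a, b) {
  out <- unique(do.call(rbind, lapply(seq_len(nrow(a)), function(i)
    sweep(b, 2, -a[i, ], "-"))))
  out
}

## Pixel-loop binary erosion with zero padding, arbitrary offsets.
brute_erode <- function(mask, offsets) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(FALSE, nr, nc)
  for (y in seq_len(nr)) for (x in seq_len(nc)) {
    if (!mask[y, x]) next
    keep <- TRUE
    for (i in seq_len(nrow(offsets))) {
      yy <- y + offsets[i, 1]; xx <- x + offsets[i, 2]
      if (yy < 1 || yy > nr || xx < 1 || xx > nc || !mask[yy, xx]) {
        keep <- FALSE
        break
      }
    }
    out[y, x] <- keep
  }
  out
}

## Pixel-loop sum of an image over a logical mask, accumulating in
## column-major order like the oracle iteration itself.
brute_mask_sum <- function(image, mask) {
  vals <- numeric(0)
  for (x in seq_len(ncol(mask))) for (y in seq_len(nrow(mask)))
    if (mask[y, x]) vals <- c(vals, image[y, x])
  sum(vals)
}

## Jaccard index between two logical masks.
jaccard <- function(a, b) sum(a & b) / sum(a | b)

## Best-match Jaccard of every truth label against a segmentation.
match_jaccard <- function(truth, seg) {
  ids <- setdiff(sort(unique(as.integer(truth))), 0L)
  vapply(ids, function(id) {
    tm <- truth == id
    cand <- setdiff(unique(seg[tm]), 0L)
    if (length(cand) == 0) return(0)
    max(vapply(cand, function(s) jaccard(tm, seg == s), numeric(1)))
  }, numeric(1))
}

## Exhaustive hypergeometric upper tail by enumerating all n-subsets of a
## universe of size N with K marked elements (N small).
enum_hyper_tail <- function(N, K, n, k) {
  subsets <- combn(N, n)
  marked <- seq_len(K)
  hits <- apply(subsets, 2, function(s) sum(s %in% marked))
  mean(hits >= k)
}

## Naive agglomerative clustering (complete linkage) on a column matrix;
## returns merge heights in order.
brute_complete_heights <- function(m) {
  clusters <- lapply(seq_len(ncol(m)), function(i) i)
  pdist <- function(a, b) {
    max(vapply(a, function(i) max(vapply(b, function(j)
      sqrt(sum((m[, i] - m[, j])^2)), numeric(1))), numeric(1)))
  }
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1))
      for (j in (i + 1):length(clusters)) {
        d <- pdist(clusters[[i]], clusters[[j]])
        if (d < best[1]) best <- c(d, i, j)
      }
    heights <- c(heights, best[1])
    clusters[[best[2]]] <- c(clusters[[best[2]]], clusters[[best[3]]])
    clusters[[best[3]]] <- NULL
  }
  heights
}

## Small random label mask: a few non-overlapping discs in a <=64x64 grid.
random_label_field <- function(seed, max_dim = 64L) {
  set.seed(seed)
  h <- sample(44:max_dim, 1); w <- sample(44:max_dim, 1)
  make_field(field_spec(height_px = h, width_px = w,
                        n_cells = sample(1:3, 1),
                        cell_radius_mean = 6, cell_radius_sd = 0.8,
                        rim_width_px = 2L, pm_fraction = 0.7,
                        seed = seed))
}
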