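# Shared fixtures: a small phantom spec that keeps unit tests fast, a raw
# series writer, and the exhaustive Otsu oracle used to cross-check the
# histogram implementation.

tiny_spec <- function(...) {
  phantom_spec(dims = c(16L, 16L, 8L), semi_axes = c(5, 6, 3), ...)
}

# write one synthetic series under root/sub-XX[/ses-YY]/<name>/
write_series <- function(root, subject, session = NULL, name, vol,
                         base_meta = list(), uid = NULL, ...) {
  d <- if (is.null(session)) {
    file.path(root, paste0("sub-", subject), name)
  } else {
    file.path(root, paste0("sub-", subject), paste0("ses-", session), name)
  }
  if (is.null(uid)) uid <- paste0("1.2.826.0.1.3680043.10.9999.",
                                  subject, ".", session %||% 0, ".",
                                  abs(sum(utf8ToInt(name))))
  write_synthetic_dicom(vol, d, base_meta, series_uid = uid, ...)
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive between-class-variance search over every histogram cut point;
# independent of the cumulative-sum implementation it checks
otsu_brute_force <- function(counts, mids) {
  stopifnot(length(counts) == length(mids))
  width <- if (length(mids) > 1) mids[2] - mids[1] else 1
  edges <- c(mids - width / 2, mids[length(mids)] + width / 2)
  n <- sum(counts)
  best_k <- NA_integer_
  best <- -Inf
  for (k in seq_len(length(counts) - 1L)) {
    c0 <- counts[1:k]; c1 <- counts[(k + 1):length(counts)]
    w0 <- sum(c0) / n; w1 <- sum(c1) / n
    if (w0 == 0 || w1 == 0) next
    mu0 <- sum(c0 * mids[1:k]) / sum(c0)
    mu1 <- sum(c1 * mids[(k + 1):length(mids)]) / sum(c1)
    bcv <- w0 * w1 * (mu0 - mu1)^2
    if (bcv > best) { best <- bcv; best_k <- k }
  }
  edges[best_k + 1L]
}
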