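#' @rdname ldR2
setMethod("ldR2", "LdReference", function(ld, a, b) {
  stopifnot(length(a) == 1L)
  out <- numeric(length(b))
  if (length(ld@dosages)) {
    da <- ld@dosages[, a]
    for (i in seq_along(b)) {
      if (b[i] == a) { out[i] <- 1; next }
      r <- suppressWarnings(cor(da, ld@dosages[, b[i]]))
      out[i] <- if (is.na(r)) NA_real_ else r^2
    }
  } else {
    key <- pairKey(rep(a, length(b)), b)
    out <- unname(ld@r2map[key])
    out[b == a] <- 1
  }
  out
})

#' @rdname ldR2
setMethod("hasRsid", "LdReference", function(ld, rsids) {
  rsids %in% ld@rsids
})
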