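# Second independent labelling oracle: minimum-label propagation. Each
# foreground pixel starts with its own linear index as label; labels are
# repeatedly replaced by the minimum over the 8-neighbourhood until a fixed
# point. Vectorised, so usable on hundreds of masks.
oracle_label_propagation <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(Inf, h, w)
  lab[mask] <- which(mask)
  shift_min <- function(l) {
    pad <- matrix(Inf, h + 2, w + 2)
    pad[2:(h + 1), 2:(w + 1)] <- l
    out <- l
    for (dy in -1:1) for (dx in -1:1) {
      out <- pmin(out, pad[(2 + dy):(h + 1 + dy), (2 + dx):(w + 1 + dx)])
    }
    out[!mask] <- Inf
    out
  }
  repeat {
    nxt <- shift_min(lab)
    if (identical(nxt, lab)) break
    lab <- nxt
  }
  lab[!mask] <- 0
  # renumber to 1..k
  u <- sort(unique(lab[lab > 0]))
  lab[lab > 0] <- match(lab[lab > 0], u)
  lab
}
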