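# Brute-force max-margin separator for tiny 2-class 2-D point sets: grid
# search over boundary orientations, each with its optimal offset, maximising
# the worst-case margin. Independent of the SVM solver.
brute_max_margin <- function(xa, xb) {
  best <- list(margin = -Inf)
  for (theta in seq(0, pi, by = 0.005)) {
    w <- c(cos(theta), sin(theta))
    pa <- xa %*% w; pb <- xb %*% w
    # orient so class b projects higher
    if (max(pa) > min(pb)) { w <- -w; pa <- -pa; pb <- -pb }
    margin <- (min(pb) - max(pa)) / 2
    if (margin > best$margin) {
      best <- list(margin = margin, w = w, b = -(max(pa) + min(pb)) / 2)
    }
  }
  best
}
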