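# internal helpers

stopWithClass <- function(msg, class, call. = FALSE) {
  cond <- structure(class = c(class, "hepasegError", "error", "condition"),
                    list(message = msg, call = if (call.) sys.call(-1)))
  stop(cond)
}

asPixelMatrix <- function(img) {
  if (is(img, "SliceImage")) img@pixels else as.matrix(img)
}

# EBImage-backed 2D resize; first index rows, second columns.
resizeMatrix <- function(m, targetDim, order = c("bilinear", "nearest")) {
  order <- match.arg(order)
  if (identical(dim(m), as.integer(targetDim))) return(m)
  filt <- if (order == "bilinear") "bilinear" else "none"
  out <- EBImage::resize(m, w = targetDim[1], h = targetDim[2],
                         filter = filt)
  matrix(as.numeric(out), targetDim[1], targetDim[2])
}
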