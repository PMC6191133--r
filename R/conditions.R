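## Classed error conditions so callers (and tests) can distinguish failure
## modes without matching message text.

cqStop <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("CombQuant_", class), "CombQuant_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

cqWarn <- function(class, msg) {
  warning(structure(
    class = c(paste0("CombQuant_", class), "CombQuant_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

invalidImage    <- function(msg) cqStop("invalid_image", msg, sys.call(-1))
invalidGeometry <- function(msg) cqStop("invalid_geometry", msg, sys.call(-1))
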