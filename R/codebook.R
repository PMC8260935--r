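#' Gesture codebook
#'
#' The decoding task distinguishes nine hand gestures out of the 32 possible
#' binary five-finger states: the five single-finger flexions, an index
#' pinch, a tripod pinch, a full fist, and rest. Each gesture is encoded as
#' a 5-bit finger-state vector. Bit order is explicit and configurable
#' because published gesture strings are ambiguous about it: the default
#' order is thumb-first (`thumb, index, middle, ring, little`).
#'
#' The index-pinch code is stored as the literal string `"00011"`; note that
#' under thumb-first ordering this names the (ring, little) bits. The tripod
#' pinch is encoded anatomically as thumb+index+middle (`"11100"`).
#'
#' @param bit_order character vector of the five finger names in bit order.
#' @return A list of `gesture_code` objects, each with `$name` and
#'   `$finger_state` (integer vector of length 5 in `bit_order`).
#' @examples
#' cb <- codebook()
#' length(cb)                       # 9
#' cb[["fist"]]$finger_state        # 1 1 1 1 1
#' @export
codebook <- function(bit_order = FINGERS) {
  stopifnot(length(bit_order) == 5L, setequal(bit_order, FINGERS))
  codes <- c(
    thumb       = "10000",
    index       = "01000",
    middle      = "00100",
    ring        = "00010",
    little      = "00001",
    index_pinch = "00011",
    tripod      = "11100",
    fist        = "11111",
    rest        = "00000"
  )
  perm <- match(bit_order, FINGERS)
  out <- lapply(names(codes), function(nm) {
    bits <- as.integer(strsplit(codes[[nm]], "")[[1]])[perm]
    gesture_code(nm, bits)
  })
  names(out) <- names(codes)
  structure(out, bit_order = bit_order, class = "nd_codebook")
}

#' @rdname codebook
#' @export
FINGERS <- c("thumb", "index", "middle", "ring", "little")

#' Construct a single gesture code
#'
#' @param name gesture name
#' @param finger_state binary vector of length 5
#' @export
gesture_code <- function(name, finger_state) {
  finger_state <- as.integer(finger_state)
  stopifnot(length(finger_state) == 5L, all(finger_state %in% c(0L, 1L)))
  structure(list(name = name, finger_state = finger_state),
            class = "nd_gesture_code")
}

#' @export
print.nd_gesture_code <- function(x, ...) {
  cat(sprintf("<gesture %s: %s>\n", x$name,
              paste(x$finger_state, collapse = "")))
  invisible(x)
}

# Look a gesture up by name, with a clear error for unknown names.
lookup_gesture <- function(name, cb = codebook()) {
  if (!name %in% names(cb))
    stop(sprintf("unknown gesture name '%s' (known: %s)", name,
                 paste(names(cb), collapse = ", ")), call. = FALSE)
  cb[[name]]
}

#' Enumerate the full finger-state space
#'
#' All `2^5 = 32` binary combinations of five finger states, as a 32 x 5
#' matrix. The codebook used here covers 9 of them.
#'
#' @return integer matrix with 32 rows and 5 columns named by finger.
#' @export
finger_state_space <- function() {
  m <- as.matrix(expand.grid(rep(list(0:1), 5)))[, 5:1]
  dimnames(m) <- list(NULL, FINGERS)
  storage.mode(m) <- "integer"
  m
}
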