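#' Label and strategy codes
#'
#' Labels are immutable for the lifetime of a simulation and are encoded as
#' integers: `0` = blue, `1` = green. Strategies are encoded `1:4` in the
#' fixed order used everywhere in the package (shares, colour codes, CSV
#' columns): `1` = cooperate with all, `2` = cooperate only with green,
#' `3` = cooperate only with blue, `4` = defect all.
#'
#' @return A named integer vector mapping names to codes.
#' @examples
#' label_codes()
#' strategy_codes()
#' @export
label_codes <- function() {
  c(blue = 0L, green = 1L)
}

#' @rdname label_codes
#' @export
strategy_codes <- function() {
  c(coop_all = 1L, coop_green = 2L, coop_blue = 3L, defect_all = 4L)
}

# internal shorthand
.S_COOP_ALL <- 1L
.S_COOP_GREEN <- 2L
.S_COOP_BLUE <- 3L
.S_DEFECT <- 4L
.L_BLUE <- 0L
.L_GREEN <- 1L

#' Action of a strategy towards a label
#'
#' Evaluates the binary action rule `S(lambda)`: 1 if an agent holding
#' `strategy` donates to a partner wearing `label`, 0 otherwise. Vectorised
#' over both arguments.
#'
#' @param strategy integer strategy code(s), see [strategy_codes()].
#' @param label integer label code(s), see [label_codes()].
#' @return Integer vector of 0/1 actions.
#' @examples
#' strategy_action(strategy_codes()["coop_green"], label_codes())
#' @export
strategy_action <- function(strategy, label) {
  strategy <- as.integer(strategy)
  label <- as.integer(label)
  if (any(is.na(strategy)) || any(strategy < 1L | strategy > 4L)) {
    stop("strategy codes must be integers in 1:4")
  }
  if (any(is.na(label)) || any(label < 0L | label > 1L)) {
    stop("label codes must be 0 (blue) or 1 (green)")
  }
  as.integer(
    strategy == .S_COOP_ALL |
      (strategy == .S_COOP_GREEN & label == .L_GREEN) |
      (strategy == .S_COOP_BLUE & label == .L_BLUE)
  )
}

# map external label spellings ("green"/"blue"/"G"/"B"/0/1) to codes
.as_label_codes <- function(x) {
  if (is.numeric(x)) {
    x <- as.integer(x)
    if (any(is.na(x)) || any(x < 0L | x > 1L)) stop("numeric labels must be 0 or 1")
    return(x)
  }
  if (is.character(x)) {
    key <- toupper(substr(trimws(x), 1L, 1L))
    out <- ifelse(key == "G", 1L, ifelse(key == "B", 0L, NA_integer_))
    if (any(is.na(out))) stop("character labels must start with 'g'/'G' or 'b'/'B'")
    return(out)
  }
  stop("labels must be integer codes or character names")
}
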