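#' Memory-one strategies
#'
#' A memory-one strategy gives the probability of cooperating as a function of
#' the previous round. With full state information it has 8 entries
#' `p1_CC, p1_CD, p1_DC, p1_DD, p2_CC, p2_CD, p2_DC, p2_DD`, where `pi_aa` is
#' the probability of cooperating when the current round is in state `si`, the
#' player's own previous action was `a` and the co-player's was `a~`. Without
#' state information the strategy has 4 entries `p_CC, p_CD, p_DC, p_DD`.
#'
#' @param p numeric vector of length 8 (full information) or 4 (no
#'   information), entries in `[0, 1]`.
#' @param setting `"full"` or `"none"`; inferred from `length(p)` when omitted.
#' @returns An object of class `memory_one_strategy`: the numeric entries with
#'   a `setting` attribute.
#' @examples
#' memory_one_strategy(c(1, 0, 0, 1))          # WSLS, no information
#' strategy_wsls()
#' @export
memory_one_strategy <- function(p, setting = NULL) {
  p <- as.numeric(p)
  if (is.null(setting)) setting <- if (length(p) == 8L) "full" else "none"
  setting <- match.arg(setting, c("full", "none"))
  nexp <- if (setting == "full") 8L else 4L
  if (length(p) != nexp) {
    stop(sprintf("a %s-information strategy has %d entries", setting, nexp), call. = FALSE)
  }
  assert_probability(p, "p")
  nm <- c("CC", "CD", "DC", "DD")
  names(p) <- if (setting == "full") c(paste0("p1_", nm), paste0("p2_", nm)) else paste0("p_", nm)
  structure(p, class = "memory_one_strategy", setting = setting)
}

#' @export
print.memory_one_strategy <- function(x, ...) {
  cat("<memory-one strategy, ", attr(x, "setting"), " information> (",
      paste(unclass(x), collapse = ","), ")\n", sep = "")
  invisible(x)
}

#' @rdname memory_one_strategy
#' @export
is_deterministic_strategy <- function(p) all(unclass(p) %in% c(0, 1))

#' Embed a no-information strategy into the full-information space
#'
#' A strategy that ignores the state behaves identically in both states, so its
#' 8-entry form repeats the 4 entries for each state block.
#'
#' @param p a 4-entry [memory_one_strategy()] (8-entry input is returned
#'   unchanged).
#' @returns An 8-entry `memory_one_strategy`.
#' @export
embed_no_info <- function(p) {
  if (length(p) == 8L) return(memory_one_strategy(as.numeric(p), "full"))
  p <- memory_one_strategy(as.numeric(p), "none")
  memory_one_strategy(c(unclass(p), unclass(p)), "full")
}

#' Effective strategy under implementation errors
#'
#' With error probability `epsilon`, an intended move is flipped, so a player
#' with strategy `p` effectively plays `(1 - epsilon) * p + epsilon * (1 - p)`.
#'
#' @param p a [memory_one_strategy()] (or bare numeric vector).
#' @param epsilon error probability in `[0, 1/2)`.
#' @returns A `memory_one_strategy` of the same setting.
#' @export
effective_strategy <- function(p, epsilon) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || epsilon < 0 || epsilon >= 0.5) {
    stop("`epsilon` must be a single value in [0, 1/2)", call. = FALSE)
  }
  setting <- attr(p, "setting") %||% if (length(p) == 8L) "full" else "none"
  memory_one_strategy((1 - epsilon) * as.numeric(p) + epsilon * (1 - as.numeric(p)), setting)
}

#' Integer encoding of deterministic strategies
#'
#' Deterministic strategies are numbered by reading their entries as a binary
#' integer, most-significant bit first: bit 7 is `p1_CC` down to bit 0 being
#' `p2_DD` (8-bit, full information) or bit 3 `p_CC` down to bit 0 `p_DD`
#' (4-bit, no information). These ids are stable keys in all output tables.
#'
#' @param p a deterministic [memory_one_strategy()].
#' @param id integer id.
#' @param setting `"full"` (8-bit) or `"none"` (4-bit).
#' @returns `strategy_id()`: an integer; `strategy_from_id()`: a
#'   `memory_one_strategy`.
#' @export
strategy_id <- function(p) {
  if (!is_deterministic_strategy(p)) stop("only deterministic strategies have integer ids", call. = FALSE)
  bits <- as.integer(unclass(p))
  as.integer(sum(bits * 2^(rev(seq_along(bits)) - 1)))
}

#' @rdname strategy_id
#' @export
strategy_from_id <- function(id, setting = c("full", "none")) {
  setting <- match.arg(setting)
  nbits <- if (setting == "full") 8L else 4L
  if (id < 0 || id >= 2^nbits) stop("id out of range for this setting", call. = FALSE)
  bits <- as.integer(intToBits(id))[nbits:1]
  memory_one_strategy(bits, setting)
}

#' Deterministic strategy sets
#'
#' All deterministic memory-one strategies of a setting, in increasing id
#' order: 256 strategies with full information, 16 without. Rows of the
#' returned matrix are 8-entry strategies (no-information strategies are
#' embedded), so both sets live in the same space and can be compared.
#'
#' @param setting `"full"` or `"none"`.
#' @returns A numeric matrix (`n x 8`) with rownames the integer ids and a
#'   `setting` attribute.
#' @export
strategy_set <- function(setting = c("full", "none")) {
  setting <- match.arg(setting)
  n <- if (setting == "full") 256L else 16L
  P <- t(vapply(seq_len(n) - 1L, function(k) {
    as.numeric(embed_no_info(strategy_from_id(k, setting)))
  }, numeric(8)))
  rownames(P) <- as.character(seq_len(n) - 1L)
  attr(P, "setting") <- setting
  P
}

#' Human-readable label for a deterministic strategy
#' @param p a [memory_one_strategy()] or an 8-entry numeric vector.
#' @returns A string like `"(1,0,0,1)"` or `"(1,0,0,0;1,0,0,1)"`.
#' @export
strategy_label <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 4L) return(paste0("(", paste(p, collapse = ","), ")"))
  paste0("(", paste(p[1:4], collapse = ","), ";", paste(p[5:8], collapse = ","), ")")
}

#' Named classic strategies
#'
#' Convenience constructors for the no-information strategies discussed
#' throughout: win-stay lose-shift `(1,0,0,1)`, always defect `(0,0,0,0)`,
#' always cooperate `(1,1,1,1)` and tit-for-tat `(1,0,1,0)`.
#'
#' @returns A 4-entry [memory_one_strategy()].
#' @export
strategy_wsls <- function() memory_one_strategy(c(1, 0, 0, 1), "none")

#' @rdname strategy_wsls
#' @export
strategy_alld <- function() memory_one_strategy(c(0, 0, 0, 0), "none")

#' @rdname strategy_wsls
#' @export
strategy_allc <- function() memory_one_strategy(c(1, 1, 1, 1), "none")

#' @rdname strategy_wsls
#' @export
strategy_tft <- function() memory_one_strategy(c(1, 0, 1, 0), "none")

`%||%` <- function(a, b) if (is.null(a)) b else a
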