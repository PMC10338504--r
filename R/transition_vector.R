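#' Environmental transition vectors
#'
#' A transition vector holds the six probabilities that govern how the
#' environment moves between the two states. Entry `qi_aa` is the probability
#' that the next round takes place in the more profitable state `s1`, given
#' that the current round is in state `si` and the players chose the action
#' pair `aa`. Transitions depend only on the number of cooperators, so the
#' mixed pairs CD and DC share one entry per state.
#'
#' @param q1_CC,q1_CD,q1_DD,q2_CC,q2_CD,q2_DD probabilities in `[0, 1]`.
#'   Alternatively the first argument may be a length-6 numeric vector or a
#'   canonical string such as `"(1,0,0;1,1,1)"`.
#' @returns An object of class `transition_vector`: a named length-6 numeric
#'   vector in the order `q1_CC, q1_CD, q1_DD, q2_CC, q2_CD, q2_DD`.
#' @examples
#' transition_vector(1, 0, 0, 1, 1, 1)        # "timeout" game
#' transition_vector("(1,0,0;1,1,0)")         # timeout with conditional return
#' @export
transition_vector <- function(q1_CC, q1_CD = NULL, q1_DD = NULL,
                              q2_CC = NULL, q2_CD = NULL, q2_DD = NULL) {
  if (is.character(q1_CC)) {
    q <- parse_transition_vector(q1_CC)
  } else if (length(q1_CC) == 6L && is.null(q1_CD)) {
    q <- as.numeric(q1_CC)
  } else {
    q <- c(q1_CC, q1_CD, q1_DD, q2_CC, q2_CD, q2_DD)
  }
  if (length(q) != 6L) stop("a transition vector has exactly 6 entries", call. = FALSE)
  assert_probability(q, "q")
  structure(setNames(as.numeric(q),
                     c("q1_CC", "q1_CD", "q1_DD", "q2_CC", "q2_CD", "q2_DD")),
            class = "transition_vector")
}

parse_transition_vector <- function(s) {
  s <- gsub("[()\\s]", "", s, perl = TRUE)
  parts <- strsplit(s, ";", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts <- c(parts, "")
  vals <- suppressWarnings(as.numeric(unlist(strsplit(parts, ",", fixed = TRUE))))
  if (length(vals) != 6L || anyNA(vals)) {
    stop("cannot parse transition vector; expected \"(q1cc,q1cd,q1dd;q2cc,q2cd,q2dd)\"",
         call. = FALSE)
  }
  vals
}

#' Canonical string form of a transition vector
#'
#' @param q a [transition_vector()].
#' @param digits significant digits used for non-integer entries.
#' @returns A string such as `"(1,0,0;1,1,1)"`, parseable by
#'   [transition_vector()].
#' @export
format_transition_vector <- function(q, digits = 6) {
  q <- unclass(transition_vector(q))
  s <- vapply(q, function(x) trimws(formatC(x, digits = digits, format = "g")), character(1))
  paste0("(", paste(s[1:3], collapse = ","), ";", paste(s[4:6], collapse = ","), ")")
}

#' @export
format.transition_vector <- function(x, ...) format_transition_vector(x)

#' @export
print.transition_vector <- function(x, ...) {
  cat("<transition vector> ", format_transition_vector(x), "\n", sep = "")
  invisible(x)
}

#' Predicates on transition vectors
#'
#' `is_deterministic()` is true when every entry is 0 or 1;
#' `is_single_stochastic()` when exactly one entry lies strictly between 0 and
#' 1; `has_absorbing_state()` when one of the two environmental states can
#' never be left (all state-1 entries equal 1, or all state-2 entries equal 0).
#'
#' @param q a [transition_vector()].
#' @returns A logical scalar.
#' @export
is_deterministic <- function(q) {
  q <- unclass(transition_vector(q))
  all(q %in% c(0, 1))
}

#' @rdname is_deterministic
#' @export
is_single_stochastic <- function(q) {
  q <- unclass(transition_vector(q))
  sum(q > 0 & q < 1) == 1L
}

#' @rdname is_deterministic
#' @export
has_absorbing_state <- function(q) {
  q <- unclass(transition_vector(q))
  all(q[1:3] == 1) || all(q[4:6] == 0)
}

#' Enumerate deterministic transition vectors
#'
#' @returns A tibble with 64 rows: the canonical string `q`, the six entries,
#'   and the predicates from [is_deterministic()].
#' @export
enumerate_deterministic_q <- function() {
  grid <- expand.grid(rep(list(c(0, 1)), 6))[, 6:1]
  names(grid) <- c("q1_CC", "q1_CD", "q1_DD", "q2_CC", "q2_CD", "q2_DD")
  qs <- apply(as.matrix(grid), 1, function(r) format_transition_vector(transition_vector(r)))
  tibble::tibble(q = qs) |>
    dplyr::bind_cols(tibble::as_tibble(grid)) |>
    dplyr::mutate(absorbing = apply(as.matrix(grid), 1, function(r) has_absorbing_state(transition_vector(r))),
                  state_independent = .data$q1_CC == .data$q2_CC &
                    .data$q1_CD == .data$q2_CD & .data$q1_DD == .data$q2_DD)
}

#' Symmetry maps on the space of transition vectors
#'
#' Two relabelings leave the weak-selection analysis essentially unchanged:
#'
#' * `action_swap()` relabels cooperation and defection. The action pair CC
#'   becomes DD (and vice versa), so within each state the CC and DD entries
#'   trade places. Because relabeling actions also turns every cooperation
#'   rate \eqn{\gamma} into \eqn{1 - \gamma}, the weak-selection value of
#'   information of the swapped game is the negative of the original.
#' * `state_swap()` relabels the two environmental states. Since entries are
#'   probabilities of moving to state 1, the two state blocks trade places and
#'   every probability is complemented. The weak-selection value of
#'   information is unchanged.
#'
#' `symmetry_orbit()` returns the orbit of `q` under the group generated by
#' both maps (at most 4 vectors); `symmetry_classes()` partitions all 64
#' deterministic vectors into their 24 orbits.
#'
#' @param q a [transition_vector()].
#' @returns `action_swap()`/`state_swap()`: a `transition_vector`;
#'   `symmetry_orbit()`: a character vector of canonical strings;
#'   `symmetry_classes()`: a tibble with columns `q` and `class_representative`.
#' @export
action_swap <- function(q) {
  q <- unclass(transition_vector(q))
  transition_vector(q[c(3, 2, 1, 6, 5, 4)])
}

#' @rdname action_swap
#' @export
state_swap <- function(q) {
  q <- unclass(transition_vector(q))
  transition_vector(1 - q[c(4, 5, 6, 1, 2, 3)])
}

#' @rdname action_swap
#' @export
symmetry_orbit <- function(q) {
  q <- transition_vector(q)
  orbit <- list(q, action_swap(q), state_swap(q), state_swap(action_swap(q)))
  sort(unique(vapply(orbit, format_transition_vector, character(1))))
}

#' @rdname action_swap
#' @export
symmetry_classes <- function() {
  det <- enumerate_deterministic_q()
  reps <- vapply(det$q, function(s) symmetry_orbit(transition_vector(s))[1], character(1))
  tibble::tibble(q = det$q, class_representative = unname(reps))
}

#' Enumerate single-stochastic transition-vector families
#'
#' A single-stochastic vector has exactly one entry strictly inside (0, 1).
#' A *family* fixes which of the six positions is stochastic and the 0/1
#' values of the remaining five entries, leaving the stochastic entry as a free
#' parameter; there are `6 * 2^5 = 192` families.
#'
#' @returns A tibble with 192 rows: `family` (canonical string with the free
#'   entry written as `q`), `position` (1-6, index of the stochastic entry),
#'   the five fixed entries, and `absorbing` (whether the family has an
#'   absorbing state for every interior value of the free entry, in which case
#'   state information is neutral for the whole family).
#' @export
enumerate_single_stochastic_families <- function() {
  rows <- list()
  det5 <- as.matrix(expand.grid(rep(list(c(0, 1)), 5))[, 5:1])
  k <- 0L
  for (pos in 1:6) {
    for (r in seq_len(nrow(det5))) {
      k <- k + 1L
      qfix <- numeric(6)
      qfix[-pos] <- det5[r, ]
      qfix[pos] <- NA
      # absorbing for all interior values of the free entry: the block not
      # containing the free entry must be absorbing on its own
      abs_flag <- if (pos <= 3) all(qfix[4:6] == 0) else all(qfix[1:3] == 1)
      lab <- qfix
      lab[pos] <- NA
      labs <- ifelse(is.na(lab), "q", as.character(lab))
      fam <- paste0("(", paste(labs[1:3], collapse = ","), ";",
                    paste(labs[4:6], collapse = ","), ")")
      rows[[k]] <- tibble::tibble(
        family = fam, position = pos,
        q1_CC = qfix[1], q1_CD = qfix[2], q1_DD = qfix[3],
        q2_CC = qfix[4], q2_CD = qfix[5], q2_DD = qfix[6],
        absorbing = abs_flag
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Instantiate a single-stochastic family at a value of its free entry
#'
#' @param family one row of [enumerate_single_stochastic_families()], or a
#'   family string such as `"(1,0,0;q,0,0)"`.
#' @param value value in `(0, 1)` for the stochastic entry.
#' @returns A [transition_vector()].
#' @export
family_at <- function(family, value) {
  if (is.character(family)) {
    s <- gsub("[()\\s]", "", family, perl = TRUE)
    vals <- unlist(strsplit(gsub(";", ",", s), ",", fixed = TRUE))
    qfix <- suppressWarnings(as.numeric(vals))
    pos <- which(vals == "q")
    if (length(pos) != 1L) stop("family string must contain exactly one free entry 'q'", call. = FALSE)
    qfix[pos] <- value
    return(transition_vector(qfix))
  }
  q <- c(family$q1_CC, family$q1_CD, family$q1_DD,
         family$q2_CC, family$q2_CD, family$q2_DD)
  q[family$position] <- value
  transition_vector(q)
}
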