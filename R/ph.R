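# Rule-based catechol/quinone redox state of DOPA versus pH and the
# resulting qualitative adhesion call.  An explicit step-function
# model: below the oxidation threshold DOPA is in the reduced catechol
# state (two ring hydroxyls, hydrogen-bond donor, adhesive); above it,
# auto-oxidation yields the quinone (C=O, no donors, non-adhesive).

#' pH rules for DOPA redox state and adhesion
#'
#' @param oxidation_pH pH above which DOPA is assigned the quinone
#'   state.  Default 6.5: between the adhesive pH 5 and non-adhesive
#'   pH 7.4 regimes; no titration curve is fitted.
#' @param strong_acid_pH pH below which the expanded-surface regime is
#'   flagged in the notes.
#' @param hbond_donors_per_catechol Hydrogen-bond donors contributed by
#'   each catechol (two ring hydroxyls).
#' @return Object of class `ph_rules`.
#' @export
ph_rules <- function(oxidation_pH = 6.5, strong_acid_pH = 3.5,
                     hbond_donors_per_catechol = 2L) {
  if (strong_acid_pH >= oxidation_pH) {
    stop("strong_acid_pH must be below oxidation_pH")
  }
  if (oxidation_pH < 0 || oxidation_pH > 14 ||
      strong_acid_pH < 0 || strong_acid_pH > 14) {
    stop("pH thresholds must lie within 0-14")
  }
  structure(list(oxidation_pH = oxidation_pH,
                 strong_acid_pH = strong_acid_pH,
                 hbond_donors_per_catechol =
                   as.integer(hbond_donors_per_catechol)),
            class = "ph_rules")
}

#' DOPA redox state at a given pH
#'
#' @param pH pH value in 0-14.
#' @param rules A [ph_rules()].
#' @return `"catechol"` or `"quinone"`.
#' @export
dopa_state <- function(pH, rules = ph_rules()) {
  stopifnot(inherits(rules, "ph_rules"))
  if (!is.numeric(pH) || length(pH) != 1L || is.na(pH) ||
      pH < 0 || pH > 14) {
    stop("pH must be a single value within 0-14")
  }
  if (pH <= rules$oxidation_pH) "catechol" else "quinone"
}

#' Qualitative adhesion assessment
#'
#' Adhesive if and only if DOPA is present and in the catechol state;
#' the quinone carries no hydrogen-bond donors and forms no adhesive
#' bond to the substrate.  An unmodified protein (`n_dopa = 0`) is
#' never called adhesive, at any pH.
#'
#' @param n_dopa Number of DOPA residues (>= 0).
#' @param pH pH value in 0-14.
#' @param rules A [ph_rules()].
#' @return Object of class `adhesion_assessment` with fields `pH`,
#'   `state`, `hbond_donors`, `adhesive`, `notes`.
#' @export
assess_adhesion <- function(n_dopa, pH, rules = ph_rules()) {
  n_dopa <- as.integer(n_dopa)
  if (is.na(n_dopa) || n_dopa < 0L) stop("n_dopa must be >= 0")
  state <- dopa_state(pH, rules)
  donors <- if (state == "catechol") {
    n_dopa * rules$hbond_donors_per_catechol
  } else 0L
  notes <- character(0L)
  if (pH < rules$strong_acid_pH) {
    notes <- c(notes, "strong-acid regime: expanded surface expected")
  }
  if (n_dopa == 0L) notes <- c(notes, "unmodified (no DOPA)")
  if (state == "quinone") {
    notes <- c(notes, "auto-oxidized quinone: no hydrogen-bond donors")
  }
  structure(list(pH = pH, state = state, hbond_donors = donors,
                 adhesive = state == "catechol" && n_dopa > 0L,
                 notes = paste(notes, collapse = "; ")),
            class = "adhesion_assessment")
}

#' @export
print.adhesion_assessment <- function(x, ...) {
  cat(sprintf("<adhesion> pH %.1f: %s, %d H-bond donor(s), %s\n",
              x$pH, x$state, x$hbond_donors,
              if (x$adhesive) "adhesive" else "non-adhesive"))
  if (nzchar(x$notes)) cat("  ", x$notes, "\n", sep = "")
  invisible(x)
}

#' Adhesion assessments over a pH series
#'
#' @param n_dopa Number of DOPA residues.
#' @param pH_list Numeric vector of pH values (non-empty).
#' @param rules A [ph_rules()].
#' @return Data frame with one row per pH: `pH`, `state`,
#'   `hbond_donors`, `adhesive`, `notes`.
#' @export
ph_series <- function(n_dopa, pH_list = c(3, 5, 7.4, 9),
                      rules = ph_rules()) {
  if (length(pH_list) == 0L) stop("pH_list must be non-empty")
  rows <- lapply(pH_list, function(p) {
    a <- assess_adhesion(n_dopa, p, rules)
    data.frame(pH = a$pH, state = a$state, hbond_donors = a$hbond_donors,
               adhesive = a$adhesive, notes = a$notes,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
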