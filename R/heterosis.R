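## Growth-trait summaries, one-way ANOVA across lines, and better-parent
## heterosis indices.

#' Per-line trait summaries (mean and standard error)
#'
#' @param traits Data frame with `line_id`, `age`, `trait`, `value`
#'   columns (e.g. from [simulate_trait_table()]).
#' @return Data frame `(line_id, age, trait, n, mean, se)` with
#'   `se = sd / sqrt(n)`; cells with fewer than 2 observations are
#'   omitted with a warning.
#' @export
trait_summary <- function(traits) {
  stopifnot(all(c("line_id", "age", "trait", "value") %in% names(traits)))
  key <- interaction(traits$line_id, traits$age, traits$trait,
                     drop = TRUE)
  pieces <- lapply(split(traits, key), function(d) {
    data.frame(line_id = d$line_id[1L], age = d$age[1L],
               trait = d$trait[1L], n = nrow(d), mean = mean(d$value),
               se = sd(d$value) / sqrt(nrow(d)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  thin <- out$n < 2L
  if (any(thin)) {
    warning(sum(thin), " cell(s) with fewer than 2 observations omitted")
    out <- out[!thin, , drop = FALSE]
  }
  out[order(out$trait, out$age, out$line_id), , drop = FALSE]
}

#' One-way ANOVA of a trait across lines
#'
#' Standard between/within decomposition (`value ~ line_id`) for one
#' age and trait.
#'
#' @param traits Trait data frame.
#' @param age,trait Cell selectors.
#' @return List `(F, p, df_between, df_within, degenerate)`. When the
#'   within-group variance is zero the F statistic is undefined and
#'   `degenerate` is `TRUE`.
#' @export
oneway_anova <- function(traits, age, trait) {
  d <- traits[traits$age == age & traits$trait == trait, , drop = FALSE]
  lines <- unique(d$line_id)
  if (length(lines) < 2L) stop("ANOVA needs at least 2 lines")
  reps <- table(d$line_id)
  if (any(reps < 2L)) stop("ANOVA needs >= 2 replicates per line")
  fit <- aov(value ~ line_id, data = d)
  tab <- suppressWarnings(anova(fit))
  Fv <- tab[["F value"]][1L]
  pv <- tab[["Pr(>F)"]][1L]
  ## a within-group mean square at machine-noise scale means the F
  ## ratio is numerically undefined (e.g. all observations identical)
  msw <- tab[["Mean Sq"]][2L]
  degenerate <- !is.finite(Fv) ||
    msw < 100 * .Machine$double.eps * mean(d$value)^2
  list(F = Fv, p = pv, df_between = tab$Df[1L], df_within = tab$Df[2L],
       degenerate = degenerate)
}

#' Better-parent heterosis
#'
#' `H = (F1 - Ps) / Ps * 100`, with `Ps` the higher parental trait
#' mean; also reports the mid-parent value `MPV = (P1 + P2) / 2`.
#' Negative H means the hybrid falls short of the better parent.
#'
#' @param f1_mean Hybrid trait mean (vectorized over hybrids).
#' @param p1_mean,p2_mean Parental trait means (must be positive).
#' @param line_id Optional hybrid labels.
#' @param trait Optional trait label carried through.
#' @return Data frame `(line_id, trait, f1_mean, ps, mpv, heterosis_pct)`.
#' @examples
#' heterosis_over_higher_parent(11.255, 10.0, 9.0)  # H = 12.55
#' @export
heterosis_over_higher_parent <- function(f1_mean, p1_mean, p2_mean,
                                         line_id = NULL,
                                         trait = NA_character_) {
  if (any(p1_mean <= 0) || any(p2_mean <= 0))
    stop("parent means must be positive")
  ps <- pmax(p1_mean, p2_mean)
  if (is.null(line_id)) line_id <- paste0("F1_", seq_along(f1_mean))
  data.frame(line_id = line_id, trait = trait, f1_mean = f1_mean,
             ps = ps, mpv = (p1_mean + p2_mean) / 2,
             heterosis_pct = (f1_mean - ps) / ps * 100,
             stringsAsFactors = FALSE)
}

#' Heterosis table for a trait panel
#'
#' Computes per-hybrid better-parent heterosis for every age and trait
#' in a trait table, using the per-cell parental means (the higher
#' parent is re-identified per trait and age).
#'
#' @param traits Trait data frame.
#' @param parents Character vector of the two parental line ids.
#' @return Data frame of [heterosis_over_higher_parent()] rows with
#'   `age` attached.
#' @export
heterosis_table <- function(traits, parents = c("P1", "P2")) {
  sm <- trait_summary(traits)
  out <- list()
  for (tr in unique(sm$trait)) for (a in unique(sm$age)) {
    cell <- sm[sm$trait == tr & sm$age == a, , drop = FALSE]
    p <- cell[match(parents, cell$line_id), "mean"]
    if (anyNA(p)) next
    hyb <- cell[!cell$line_id %in% parents, , drop = FALSE]
    if (nrow(hyb) == 0L) next
    h <- heterosis_over_higher_parent(hyb$mean, p[1L], p[2L],
                                      line_id = hyb$line_id, trait = tr)
    h$age <- a
    out[[length(out) + 1L]] <- h
  }
  do.call(rbind, out)
}
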