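## Step-growth (most-probable) chain-length distribution used as the ground
## truth for the SEC stage. Split-intein ligation of identical protein
## subunits is, statistically, a step-growth polymerization: at extent of
## reaction p the number fraction of i-mers is (1-p) p^(i-1).

#' Flory most-probable molecular-weight distribution
#'
#' Generates the discrete chain-length distribution of ideal step-growth
#' polymerization at extent of reaction `p`, with per-degree number fractions
#' and closed-form number/mass-average molecular weights. The distribution is
#' truncated at `i_max` chains; the truncation must capture at least
#' `1 - mass_tol` of the total mass, otherwise an error reports the degree
#' that would be required.
#'
#' The untruncated closed forms are `Mn = M0/(1-p)` and
#' `Mw = M0 (1+p)/(1-p)`; the returned `true_mn`/`true_mw` are the truncated
#' (renormalized) sums, which agree with the closed forms to the level
#' implied by `mass_tol`.
#'
#' @param p extent of reaction, in `[0, 1)`
#' @param monomer_mass monomer molecular mass M0 in kDa
#' @param i_max maximum degree of polymerization retained; `NULL` (default)
#'   chooses the smallest degree capturing `1 - mass_tol` of the mass
#' @param mass_tol maximum tolerated truncated mass fraction (default 1e-8)
#' @return object of class `flory_distribution`: list with `monomer_mass`,
#'   `p`, `i_max`, `degrees`, `masses` (kDa), `number_fractions` (sum 1),
#'   `mass_fractions`, `true_mn`, `true_mw` (kDa), and the untruncated
#'   closed forms `mn_closed`, `mw_closed`
#' @examples
#' d <- gen_flory_distribution(0.5, 43)
#' c(d$true_mn, d$true_mw)  # 86, 129 kDa
#' @export
gen_flory_distribution <- function(p, monomer_mass, i_max = NULL,
                                   mass_tol = 1e-8) {
  check_scalar(p, "p", lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar(monomer_mass, "monomer_mass", lower = 0, strict_lower = TRUE)
  check_scalar(mass_tol, "mass_tol", lower = 0, upper = 1,
               strict_lower = TRUE)

  if (p == 0) {
    i_max <- 1L
  } else {
    # Mass (weight) fraction of an i-mer: w_i = i (1-p)^2 p^(i-1).
    # Tail mass beyond n: p^n (1 + n(1-p)).
    tail_mass <- function(n) p^n * (1 + n * (1 - p))
    required <- 1L
    while (tail_mass(required) > mass_tol) required <- required * 2L
    lo <- required %/% 2L
    while (lo < required) {  # bisect to the smallest adequate degree
      mid <- (lo + required) %/% 2L
      if (tail_mass(mid) > mass_tol) lo <- mid + 1L else required <- mid
    }
    if (is.null(i_max)) {
      i_max <- required
    } else {
      i_max <- as.integer(i_max)
      check_scalar(i_max, "i_max", lower = 1)
      if (tail_mass(i_max) > mass_tol)
        stop_invalid(paste0(
          "i_max = %d truncates %.3g of the total mass (tolerance %.3g); ",
          "i_max >= %d is required"), i_max, tail_mass(i_max), mass_tol,
          required)
    }
  }

  i <- seq_len(i_max)
  nf <- (1 - p) * p^(i - 1)
  nf <- nf / sum(nf)
  masses <- i * monomer_mass
  mf <- nf * masses
  mf <- mf / sum(mf)
  true_mn <- sum(nf * masses)
  true_mw <- sum(nf * masses^2) / sum(nf * masses)

  structure(list(
    monomer_mass = monomer_mass,
    p = p,
    i_max = i_max,
    degrees = i,
    masses = masses,
    number_fractions = nf,
    mass_fractions = mf,
    true_mn = true_mn,
    true_mw = true_mw,
    mn_closed = monomer_mass / (1 - p),
    mw_closed = monomer_mass * (1 + p) / (1 - p)
  ), class = "flory_distribution")
}

#' @export
print.flory_distribution <- function(x, ...) {
  cat(sprintf(
    "Flory distribution: p = %.4f, M0 = %.3g kDa, i_max = %d\n",
    x$p, x$monomer_mass, x$i_max))
  cat(sprintf("  Mn = %.4g kDa, Mw = %.4g kDa, dispersity = %.4f\n",
              x$true_mn, x$true_mw, x$true_mw / x$true_mn))
  invisible(x)
}
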