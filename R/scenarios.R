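#' Define a simulation scenario
#'
#' A scenario fixes the generating Box-Cox measurement-error model for a
#' synthetic repeated-recall study: on the transformed scale each person's
#' usual intake is drawn from \eqn{N(\mu, \sigma_u^2)} and each of their
#' daily observations from \eqn{N(b_i, \sigma_\epsilon^2)}; daily amounts
#' on the original scale are the inverse Box-Cox transform at `lam`.
#'
#' @param label Scenario label (the built-ins use Roman numerals I..XII).
#' @param n Number of persons (>= 2).
#' @param sigma_eps_sq Within-person (day-to-day) variance
#'   \eqn{\sigma_\epsilon^2} on the transformed scale, > 0.
#' @param sigma_u_sq Between-person variance \eqn{\sigma_u^2} on the
#'   transformed scale, >= 0.
#' @param mu Overall mean intake \eqn{\mu} on the transformed scale.
#' @param lam Box-Cox parameter \eqn{\lambda} of the generating model.
#' @param days_per_person Replicate daily recalls per person (>= 2).
#' @return A `scenario_spec` object (list) with the above fields plus
#'   `rvar`, the variance ratio \eqn{\sigma_\epsilon^2/\sigma_u^2}
#'   (`Inf` when \eqn{\sigma_u^2 = 0}).
#' @examples
#' scenario_spec("I", n = 150, sigma_eps_sq = 1, sigma_u_sq = 0.25)
#' @export
scenario_spec <- function(label, n, sigma_eps_sq, sigma_u_sq,
                          mu = 7.5, lam = 0.2, days_per_person = 2) {
  stopifnot(n >= 2, sigma_eps_sq > 0, sigma_u_sq >= 0,
            days_per_person >= 2, lam >= 0, lam <= 1)
  structure(
    list(label = as.character(label), n = as.integer(n),
         sigma_eps_sq = sigma_eps_sq, sigma_u_sq = sigma_u_sq,
         mu = mu, lam = lam,
         days_per_person = as.integer(days_per_person),
         rvar = if (sigma_u_sq > 0) sigma_eps_sq / sigma_u_sq else Inf),
    class = "scenario_spec"
  )
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf(
    "Scenario %s: n=%d, days=%d, sigma_eps^2=%g, sigma_u^2=%g (rvar=%.3g), mu=%g, lambda=%g\n",
    x$label, x$n, x$days_per_person, x$sigma_eps_sq, x$sigma_u_sq,
    x$rvar, x$mu, x$lam))
  invisible(x)
}

#' The twelve built-in simulation scenarios
#'
#' Scenario grid crossing sample sizes 150/300/500 with variance ratios
#' rvar of 4 and 9. Scenarios I-VI have within-person variance 1 and
#' between-person variance 0.25 (rvar 4) or 0.11 (rvar 9); scenarios
#' VII-XII have between-person variance 0.3 and within-person variance 1.2
#' (rvar 4) or 2.7 (rvar 9). All use mu = 7.5 and lambda = 0.2 with two
#' days per person.
#'
#' @return A named list of 12 [scenario_spec()] objects, names I..XII.
#' @export
builtin_scenarios <- function() {
  grid <- list(
    list("I",    150, 1.0,  0.25), list("II",   150, 1.0,  0.11),
    list("III",  300, 1.0,  0.25), list("IV",   300, 1.0,  0.11),
    list("V",    500, 1.0,  0.25), list("VI",   500, 1.0,  0.11),
    list("VII",  150, 1.2,  0.30), list("VIII", 150, 2.7,  0.30),
    list("IX",   300, 1.2,  0.30), list("X",    300, 2.7,  0.30),
    list("XI",   500, 1.2,  0.30), list("XII",  500, 2.7,  0.30)
  )
  specs <- lapply(grid, function(g)
    scenario_spec(g[[1]], n = g[[2]], sigma_eps_sq = g[[3]],
                  sigma_u_sq = g[[4]]))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "label"))
}

#' Generate a synthetic two-day intake dataset
#'
#' Draws each person's transformed-scale mean from
#' \eqn{N(\mu, \sigma_u^2)}, their daily values from
#' \eqn{N(b_i, \sigma_\epsilon^2)}, and back-transforms to the original
#' scale with the inverse Box-Cox at the scenario's `lam`. Each person has
#' their own random substream keyed by `(seed, replicate_index, person)`,
#' so the first `n` persons are identical whatever the total person count.
#'
#' A daily draw landing in the undefined region of the inverse transform
#' (\eqn{\lambda y + 1 \le 0}) is redrawn from the person's substream; at
#' the built-in parameters this is a ~7-sigma event. More than
#' `max_redraws` redraws for one observation aborts with an error, which
#' signals a pathological scenario rather than bad luck.
#'
#' @param spec A [scenario_spec()].
#' @param seed Integer study seed.
#' @param replicate_index Replicate number within a study (>= 1).
#' @param max_redraws Redraw budget per observation.
#' @return A tibble with columns `person` (integer), `day` (1..days),
#'   `amount` (positive original-scale intake).
#' @export
generate_dataset <- function(spec, seed, replicate_index = 1L,
                             max_redraws = 100L) {
  stopifnot(inherits(spec, "scenario_spec"))
  k <- spec$days_per_person
  amounts <- matrix(NA_real_, nrow = spec$n, ncol = k)
  for (i in seq_len(spec$n)) {
    amounts[i, ] <- with_seed(mix_seed(seed, replicate_index, i), {
      b <- stats::rnorm(1, spec$mu, sqrt(spec$sigma_u_sq))
      y <- stats::rnorm(k, b, sqrt(spec$sigma_eps_sq))
      bad <- which(spec$lam * y + 1 <= 0)
      tries <- 0L
      while (length(bad) > 0) {
        tries <- tries + 1L
        if (tries > max_redraws) {
          stop(sprintf(
            "scenario %s: inverse Box-Cox domain violated repeatedly (person %d)",
            spec$label, i))
        }
        y[bad] <- stats::rnorm(length(bad), b, sqrt(spec$sigma_eps_sq))
        bad <- bad[spec$lam * y[bad] + 1 <= 0]
      }
      bc_inverse(y, spec$lam)
    })
  }
  tibble::tibble(
    person = rep(seq_len(spec$n), each = k),
    day = rep(seq_len(k), times = spec$n),
    amount = as.vector(t(amounts))
  )
}

#' Read or write an intake dataset as delimited text
#'
#' Long format with header `person,day,amount`, UTF-8, comma-separated.
#'
#' @param data Tibble/data.frame with columns `person`, `day`, `amount`.
#' @param path File path.
#' @return `read_intake()` returns a tibble; `write_intake()` returns
#'   `path` invisibly.
#' @export
write_intake <- function(data, path) {
  stopifnot(all(c("person", "day", "amount") %in% names(data)))
  utils::write.csv(data[, c("person", "day", "amount")], path,
                   row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_intake
#' @export
read_intake <- function(path) {
  df <- utils::read.csv(path, fileEncoding = "UTF-8")
  need <- c("person", "day", "amount")
  if (!all(need %in% names(df))) {
    stop("intake file must have header columns person, day, amount")
  }
  if (any(df$amount <= 0)) stop("intake amounts must be positive")
  tibble::as_tibble(df[, need])
}

#' Read scenario definitions from a YAML file
#'
#' Each top-level entry is either a built-in label (string, e.g. `"I"`) or
#' a mapping with the [scenario_spec()] fields (`label`, `n`,
#' `sigma_eps_sq`, `sigma_u_sq`, optional `mu`, `lam`, `days_per_person`).
#'
#' @param path Path to a YAML file.
#' @return A named list of [scenario_spec()] objects.
#' @export
read_scenarios <- function(path) {
  # keep YAML-1.1 boolean-like scalars (notably the key "n") as literals
  keep <- list("bool#yes" = function(x) x, "bool#no" = function(x) x)
  raw <- yaml::read_yaml(path, handlers = keep)
  builtins <- builtin_scenarios()
  specs <- lapply(raw, function(entry) {
    if (is.character(entry) && length(entry) == 1) {
      if (!entry %in% names(builtins)) {
        stop("unknown built-in scenario label: ", entry)
      }
      builtins[[entry]]
    } else {
      do.call(scenario_spec, entry)
    }
  })
  stats::setNames(specs, vapply(specs, `[[`, character(1), "label"))
}
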