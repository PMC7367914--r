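#' Drug model configurations
#'
#' Loads a drug configuration (dose, parameter marginals with truncation
#' ranges, enzyme pathway definitions, model options) from a structured YAML
#' file.  Configurations for `"quinidine"`, `"alprazolam"` and `"midazolam"`
#' ship with the package; any file following the same schema can be given by
#' path.
#'
#' @param drug drug name (one of the bundled configurations) or a path to a
#'   YAML configuration file.
#' @return an object of class `drug_spec` with elements `name`, `dose`
#'   (mg), `molecular_weight` (g/mol), `sac_enabled`, `clearance_mode`
#'   (`"direct_clint"` or `"michaelis_menten"`), `marginals` (named list of
#'   [marginal()] objects, fixed constants included), `pathways`, and
#'   `varying` (labels of the non-fixed parameters).
#' @examples
#' qd <- drug_spec("quinidine")
#' qd$dose
#' length(qd$varying)
#' @export
drug_spec <- function(drug) {
  if (file.exists(drug)) {
    path <- drug
  } else {
    path <- system.file("extdata", paste0(drug, ".yaml"), package = "mpbpkgsa")
    if (!nzchar(path))
      stop("unknown drug '", drug, "': no bundled configuration and no such file")
  }
  cfg <- yaml::read_yaml(path)
  num <- function(x) as.numeric(x)
  margs <- list()
  for (p in cfg$parameters) {
    margs[[p$name]] <- marginal(p$name, family = p$family,
                                p1 = num(p$p1), p2 = num(p$p2),
                                lower = num(p$min), upper = num(p$max),
                                unit = p$unit %||% NA_character_)
  }
  for (p in cfg$fixed) {
    v <- num(p$value)
    margs[[p$name]] <- marginal(p$name, "fixed", value = v,
                                lower = min(v, 0), upper = max(v, 1),
                                unit = p$unit %||% NA_character_)
  }
  varying <- vapply(Filter(function(m) m$family != "fixed", margs),
                    function(m) m$name, character(1))
  mode <- match.arg(cfg$clearance_mode, c("direct_clint", "michaelis_menten"))
  if (mode == "michaelis_menten") {
    for (pw in cfg$pathways) {
      if (is.null(pw$abundance) || is.null(pw$sub))
        stop("michaelis_menten pathways need abundance and sub entries")
      for (s in pw$sub)
        if (num(s$km) <= 0 || num(s$vm) < 0)
          stop("pathway ", pw$enzyme, ": need km > 0 and vm >= 0")
    }
  }
  structure(list(
    name = cfg$name,
    dose = num(cfg$dose_mg),
    molecular_weight = num(cfg$molecular_weight),
    sac_enabled = isTRUE(cfg$sac_enabled),
    clearance_mode = mode,
    marginals = margs,
    pathways = cfg$pathways,
    varying = unname(varying),
    flows_normalized = FALSE
  ), class = "drug_spec")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.drug_spec <- function(x, ...) {
  cat(sprintf("<drug_spec> %s: %g mg oral, %s clearance, SAC %s\n",
              x$name, x$dose, x$clearance_mode,
              if (x$sac_enabled) "on" else "off"))
  cat(sprintf("  %d varying parameters, %d enzyme pathways\n",
              length(x$varying), length(x$pathways)))
  invisible(x)
}

#' Default correlation fixture for a bundled drug
#'
#' The dependence structure used alongside the printed marginals.  The
#' numeric entries are a synthetic, user-overridable fixture (no published
#' numeric correlation matrix exists for these populations); they encode the
#' qualitative structure of a simulator-derived adult population: a strong
#' liver-partition/plasma-binding link (`Kp_liver`--`f_u` = 0.9, chosen below
#' 1 so the two effects remain separable), moderate-to-strong body-weight
#' links to liver volume and the two hepatic blood flows, and moderate
#' correlations among the hepatic enzyme clearances (or abundances).
#'
#' @param drug a [drug_spec()] or a bundled drug name.
#' @param kp_fu `Kp_liver`--`f_u` correlation (default 0.9).
#' @param bw_links named vector of body-weight correlations
#'   (default `c(V_liver = 0.6, Q_HA = 0.5, Q_PV = 0.4)`).
#' @param enzyme_r pairwise correlation among enzyme clearance/abundance
#'   parameters (default 0.4).
#' @param overrides optional named list `list(c("a","b") = r, ...)` given as
#'   a data frame with columns `i`, `j`, `r` to set arbitrary extra entries.
#' @return a [correlation_spec()] over the drug's varying parameters, with
#'   attribute `source = "synthetic-fixture"`.
#' @export
default_correlation <- function(drug, kp_fu = 0.9,
                                bw_links = c(V_liver = 0.6, Q_HA = 0.5,
                                             Q_PV = 0.4),
                                enzyme_r = 0.4, overrides = NULL) {
  if (!inherits(drug, "drug_spec")) drug <- drug_spec(drug)
  lab <- drug$varying
  k <- length(lab)
  m <- diag(k)
  dimnames(m) <- list(lab, lab)
  set <- function(a, b, r) {
    if (a %in% lab && b %in% lab) { m[a, b] <<- r; m[b, a] <<- r }
  }
  set("Kp_liver", "f_u", kp_fu)
  for (nm in names(bw_links)) set("BW", nm, bw_links[[nm]])
  enz <- grep("^(CL_int_|A_)", lab, value = TRUE)
  if (length(enz) > 1)
    for (i in seq_along(enz)[-1]) for (j in seq_len(i - 1))
      set(enz[i], enz[j], enzyme_r)
  if (!is.null(overrides)) {
    for (r in seq_len(nrow(overrides)))
      set(overrides$i[r], overrides$j[r], overrides$r[r])
  }
  out <- correlation_spec(m)
  attr(out, "source") <- "synthetic-fixture"
  out
}

#' Bundled drug fixture: marginals plus correlation
#'
#' Convenience wrapper returning the printed marginals together with the
#' default synthetic correlation fixture.
#'
#' @inheritParams default_correlation
#' @param ... passed to [default_correlation()].
#' @return list with elements `drug` ([drug_spec()]) and `corr`
#'   ([correlation_spec()]).
#' @export
default_fixture <- function(drug, ...) {
  if (!inherits(drug, "drug_spec")) drug <- drug_spec(drug)
  list(drug = drug, corr = default_correlation(drug, ...))
}

#' Apply an analysis scenario to a drug fixture
#'
#' Two structural what-if variants of the baseline analysis:
#' \describe{
#'   \item{`normalized_flows`}{reparametrises the hepatic blood flows per kg
#'     body weight: `Q_HA` and `Q_PV` are replaced by `Q_HA_hat` (lognormal
#'     (-1.24, 1.44e-2) L/h/kg) and `Q_PV_hat` (lognormal(-0.11, 1.77e-2)
#'     L/h/kg), the model multiplies them by `BW`, and the body-weight--flow
#'     correlations are removed (the point of the normalisation).}
#'   \item{`independent_cyps`}{zeroes the inter-enzyme correlations while
#'     keeping all other correlations the same.}
#' }
#'
#' @param drug a [drug_spec()].
#' @param corr a [correlation_spec()] over `drug$varying`.
#' @param scenario `"baseline"`, `"normalized_flows"` or `"independent_cyps"`.
#' @return list with modified `drug` and `corr`.
#' @export
apply_scenario <- function(drug, corr,
                           scenario = c("baseline", "normalized_flows",
                                        "independent_cyps")) {
  scenario <- match.arg(scenario)
  if (scenario == "baseline") return(list(drug = drug, corr = corr))
  m <- corr$matrix
  if (scenario == "normalized_flows") {
    margs <- drug$marginals
    margs[["Q_HA"]] <- NULL; margs[["Q_PV"]] <- NULL
    margs[["Q_HA_hat"]] <- marginal("Q_HA_hat", "lognormal", -1.24, 1.44e-2,
                                    lower = 1e-6, upper = 2, unit = "L/h/kg")
    margs[["Q_PV_hat"]] <- marginal("Q_PV_hat", "lognormal", -0.11, 1.77e-2,
                                    lower = 1e-6, upper = 5, unit = "L/h/kg")
    drug$marginals <- margs
    drug$varying <- vapply(Filter(function(mm) mm$family != "fixed", margs),
                           function(mm) mm$name, character(1))
    drug$flows_normalized <- TRUE
    lab <- rownames(m)
    lab[lab == "Q_HA"] <- "Q_HA_hat"
    lab[lab == "Q_PV"] <- "Q_PV_hat"
    dimnames(m) <- list(lab, lab)
    for (fl in c("Q_HA_hat", "Q_PV_hat"))
      if (fl %in% lab && "BW" %in% lab) { m["BW", fl] <- 0; m[fl, "BW"] <- 0 }
    # reorder to match the new varying order
    m <- m[drug$varying, drug$varying]
  } else { # independent_cyps
    enz <- grep("^(CL_int_|A_)", rownames(m), value = TRUE)
    for (i in enz) for (j in enz) if (i != j) m[i, j] <- 0
  }
  list(drug = drug, corr = correlation_spec(m))
}
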