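#' Write a small frozen fixture bundle
#'
#' Generates and writes plain-text fixtures used for cross-checking: a toy
#' logistic dataset, a frozen scenario (JSON), a modest validation cohort
#' (CSV) from that scenario, and a manifest with MD5 checksums plus the toy
#' dataset's maximum-likelihood coefficients computed at generation time by a
#' general-purpose optimiser (so downstream fits can be validated against an
#' independent route).
#'
#' @param seed seed controlling the whole bundle; the same seed always yields
#'   the same files and checksums.
#' @param out output directory (created if needed).
#' @param validation_n rows in the fixture validation cohort.
#' @return (invisibly) a list with the file paths and their checksums.
#' @export
make_fixtures <- function(seed = 1L, out, validation_n = 1e4) {
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  paths <- c(toy = file.path(out, "toy_logistic.csv"),
             scenario = file.path(out, "scenario.json"),
             validation = file.path(out, "validation_cohort.csv"),
             manifest = file.path(out, "manifest.json"))
  with_seed(seed, {
    x <- round(rnorm(40), 4)
    p <- plogis(-0.3 + 0.8 * x)
    y <- rbinom(40, 1L, p)
    toy <- data.frame(x = x, y = y)
    write.csv(toy, paths[["toy"]], row.names = FALSE)

    # reference MLE by direct likelihood maximisation (not the package IRLS)
    nll <- function(b) -sum(y * (b[1] + b[2] * x) -
                              log1p(exp(b[1] + b[2] * x)))
    opt <- stats::optim(c(0, 0), nll, method = "BFGS",
                        control = list(reltol = 1e-14))

    scfg <- scenario_config(covariance_mode = "random_psd")
    scen <- sample_scenario(scfg, seed = derive_seed(seed, 11L))
    scenario_to_json(scen, paths[["scenario"]])
    val <- generate_dataset(scen, validation_n,
                            seed = derive_seed(seed, 12L))
    vdf <- as.data.frame(round(val$x, 6))
    vdf$y <- val$y
    vdf$true_p <- round(val$true_p, 8)
    write.csv(vdf, paths[["validation"]], row.names = FALSE)

    sums <- tools::md5sum(paths[c("toy", "scenario", "validation")])
    manifest <- list(seed = seed,
                     checksums = as.list(sums),
                     toy_mle = list(intercept = opt$par[1],
                                    slope = opt$par[2]))
    writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA),
               paths[["manifest"]])
    invisible(list(paths = paths, checksums = sums,
                   toy_mle = opt$par))
  })
}
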