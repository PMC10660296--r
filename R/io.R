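#' @include synthetic-data.R
NULL

#' Read and write observation tables
#'
#' Tidy CSV interchange format for noisy single-cell measurements:
#' columns \code{trajectory_id}, \code{time}, \code{species},
#' \code{value}, with every trajectory measured at the consecutive
#' integer times 0..T.  Missing interior time points raise an explicit
#' gap error (no silent imputation); a non-integer grid is rejected; all
#' trajectories must share the same T.
#'
#' @param path CSV file path.
#' @return \code{readObservations} returns an
#'   \linkS4class{ObservationSet}.
#' @export
readObservations <- function(path) {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("trajectory_id", "time", "species", "value")
    if (!all(need %in% names(df)))
        stop("observations CSV needs columns ",
             paste(need, collapse = ", "))
    if (any(df$time != round(df$time)))
        stop("non-integer time grid in ", path)
    species <- sort(unique(df$species))
    ids <- unique(df$trajectory_id)
    Ts <- vapply(split(df$time, df$trajectory_id), max, 0)[as.character(ids)]
    if (length(unique(Ts)) != 1L)
        stop("trajectories have different final times: ",
             paste(unique(Ts), collapse = ", "))
    T <- as.integer(Ts[[1L]])
    data <- lapply(ids, function(id) {
        sub <- df[df$trajectory_id == id, ]
        m <- matrix(NA_real_, length(species), T + 1L,
                    dimnames = list(species, 0:T))
        for (sp in species) {
            s <- sub[sub$species == sp, ]
            tGot <- sort(s$time)
            tWant <- 0:T
            gap <- setdiff(tWant, tGot)
            if (length(gap))
                stop(sprintf(
                    "trajectory '%s', species '%s': missing time point(s) %s",
                    id, sp, paste(head(gap, 5L), collapse = ", ")))
            m[sp, as.character(s$time)] <- s$value
        }
        m
    })
    new("ObservationSet", data = data, species = species, times = 0:T)
}

#' @rdname readObservations
#' @param obs An \linkS4class{ObservationSet}.
#' @export
writeObservations <- function(obs, path) {
    stopifnot(is(obs, "ObservationSet"))
    rows <- lapply(seq_along(obs@data), function(i) {
        m <- obs@data[[i]]
        data.frame(trajectory_id = i,
                   time = rep(obs@times, each = nrow(m)),
                   species = rep(obs@species, length(obs@times)),
                   value = as.numeric(m))
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Write simulated trajectories or reaction counts as tidy CSV
#'
#' @param trajList List of species x time matrices.
#' @param path Output CSV path.
#' @export
writeTrajectories <- function(trajList, path) {
    rows <- lapply(seq_along(trajList), function(i) {
        m <- trajList[[i]]
        data.frame(trajectory_id = i,
                   time = rep(as.integer(colnames(m)), each = nrow(m)),
                   species = rep(rownames(m), ncol(m)),
                   count = as.integer(m))
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' @rdname writeTrajectories
#' @param countsList List of reactions x interval matrices.
#' @export
writeReactionCounts <- function(countsList, path) {
    rows <- lapply(seq_along(countsList), function(i) {
        m <- countsList[[i]]
        data.frame(trajectory_id = i,
                   interval = rep(seq_len(ncol(m)), each = nrow(m)),
                   reaction = rep(rownames(m), ncol(m)),
                   count = as.integer(m))
    })
    write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Summarise posterior samples
#'
#' Per-parameter posterior mean, SD and central 95% credible interval;
#' when ground-truth values are supplied the normalised mean and SD
#' (sample / truth) are added, the convention used to compare recovery
#' across parameters of different magnitude.
#'
#' @param samples A \linkS4class{PosteriorSamples}.
#' @param truth Optional named numeric of generative values.
#' @param drop Columns to exclude (default the log-likelihood trace).
#' @return A data.frame, one row per recorded quantity.
#' @export
summarizePosterior <- function(samples, truth = NULL,
                               drop = "logObsLik") {
    stopifnot(is(samples, "PosteriorSamples"))
    d <- samples@draws
    keep <- setdiff(colnames(d), drop)
    d <- d[, keep, drop = FALSE]
    out <- data.frame(
        parameter = keep,
        mean = colMeans(d),
        sd = apply(d, 2L, sd),
        q2.5 = apply(d, 2L, quantile, 0.025),
        q97.5 = apply(d, 2L, quantile, 0.975),
        row.names = NULL)
    if (!is.null(truth)) {
        tv <- truth[out$parameter]
        out$truth <- unname(tv)
        out$normMean <- out$mean / unname(tv)
        out$normSD <- out$sd / unname(tv)
    }
    out
}

#' Format posterior estimates as mean +/- SD
#'
#' @param samples A \linkS4class{PosteriorSamples}.
#' @param parameter Column to format.
#' @param digits Decimal places.
#' @return Character scalar like \code{"12.90±0.14"}.
#' @export
formatEstimate <- function(samples, parameter, digits = 2L) {
    d <- samples@draws[, parameter]
    sprintf(paste0("%.", digits, "f±%.", digits, "f"),
            mean(d), sd(d))
}

#' Read a network configuration file
#'
#' YAML configuration in either of two dialects: the short form for the
#' built-in two-step activation model, naming \code{AX}, \code{AY},
#' \code{KM}, \code{B}, \code{tauX: [shape, rate]},
#' \code{tauY: [shape, rate]} and optionally \code{sigma_e}, \code{x0},
#' \code{y0}; or the full form with blocks \code{species},
#' \code{reactions} (each with \code{name}, \code{reactants},
#' \code{products}, \code{propensity: \{form, rate, K, substrate\}},
#' \code{delay: \{family, shapes, rates\}}), \code{init_state} and
#' \code{observed}.
#'
#' @param path YAML file path.
#' @return List with elements \code{net} (a
#'   \linkS4class{DelayedNetwork}) and \code{sigmaE}.
#' @export
readNetworkConfig <- function(path) {
    cfg <- yaml::read_yaml(path)
    if (all(c("AX", "AY", "KM", "B") %in% names(cfg))) {
        delayOf <- function(x) {
            if (is.null(x)) noDelay()
            else gammaDelay(x[[1L]], x[[2L]])
        }
        net <- buildTwoStepModel(cfg$AX, cfg$AY, cfg$KM, cfg$B,
                                 delayX = delayOf(cfg$tauX),
                                 delayY = delayOf(cfg$tauY),
                                 x0 = if (is.null(cfg$x0)) 0 else cfg$x0,
                                 y0 = if (is.null(cfg$y0)) 0 else cfg$y0)
        return(list(net = net,
                    sigmaE = if (is.null(cfg$sigma_e)) 10 else cfg$sigma_e))
    }
    stopifnot(!is.null(cfg$species), !is.null(cfg$reactions))
    rxs <- lapply(cfg$reactions, function(r) {
        dl <- r$delay
        delay <- if (is.null(dl) || identical(dl$family, "dirac_zero"))
            noDelay()
        else if (identical(dl$family, "gamma"))
            gammaDelay(dl$shapes[[1L]], dl$rates[[1L]])
        else gammaSumDelay(unlist(dl$shapes), unlist(dl$rates))
        reaction(r$name,
                 reactants = unlist(r$reactants),
                 products = unlist(r$products),
                 form = r$propensity$form,
                 rate = unlist(r$propensity$rate),
                 K = if (is.null(r$propensity$K)) NULL
                     else unlist(r$propensity$K),
                 substrate = r$propensity$substrate,
                 delay = delay)
    })
    net <- delayedNetwork(
        species = unlist(cfg$species), reactions = rxs,
        initState = if (is.null(cfg$init_state)) NULL
                    else unlist(cfg$init_state),
        observed = if (is.null(cfg$observed)) unlist(cfg$species)
                   else unlist(cfg$observed))
    list(net = net, sigmaE = if (is.null(cfg$sigma_e)) 10 else cfg$sigma_e)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seeds, package version,
#' wall-clock time and MD5 digests of the files written by a run, as a
#' JSON sidecar making command-line runs reproducible and auditable.
#'
#' @param path Output JSON path.
#' @param config Named list: configuration and seeds of the run.
#' @param files Character vector of output files to digest.
#' @param elapsed Named numeric of per-stage wall-clock seconds.
#' @return The manifest (invisibly).
#' @export
writeRunManifest <- function(path, config, files = character(0),
                             elapsed = numeric(0)) {
    manifest <- list(
        package = "DelayedKinetics",
        version = as.character(utils::packageVersion("DelayedKinetics")),
        timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
        config = config,
        elapsed_sec = as.list(elapsed),
        outputs = if (length(files))
            lapply(setNames(as.list(files), basename(files)), function(f)
                list(path = f, md5 = unname(tools::md5sum(f))))
        else list())
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    invisible(manifest)
}
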