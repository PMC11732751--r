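#' Read and write station profiles as CSV
#'
#' Long-format CSV with columns `station`, `lon`, `depth_m`, `T_C`,
#' `SA_gkg`, `NO3_umolkg` (nitrate column present only when available).
#'
#' @param profiles list of [ocean_profile()] objects
#' @param path CSV file path
#' @return `read_profiles_csv` returns a list of `ocean_profile`s;
#'   `write_profiles_csv` returns `path` invisibly
#' @export
write_profiles_csv <- function(profiles, path) {
  rows <- lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    df <- data.frame(station = i, lon = p$lon, depth_m = p$depth,
                     T_C = p$temperature, SA_gkg = p$salinity)
    if (!is.null(p$nitrate)) df$NO3_umolkg <- p$nitrate
    df
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profiles_csv
#' @export
read_profiles_csv <- function(path) {
  df <- utils::read.csv(path)
  lapply(split(df, df$station), function(d) {
    ocean_profile(depth = d$depth_m, temperature = d$T_C,
                  salinity = d$SA_gkg,
                  nitrate = if ("NO3_umolkg" %in% names(d)) d$NO3_umolkg,
                  lon = d$lon[1], lat = 0)
  })
}

#' Read and write gridded fields as long-format CSV
#'
#' Depth-by-axis matrices are serialized as `axis`, `depth_m`, one column
#' per variable. Used for velocity sections and derived fields in place of
#' NetCDF; the format round-trips values and grid exactly.
#'
#' @param field a [velocity_field()] (for `write_velocity_csv`) or the path
#'   of a file written by it
#' @param path CSV file path
#' @return the written path / the reconstructed `velocity_field`
#' @export
write_velocity_csv <- function(field, path) {
  df <- data.frame(axis = rep(field$axis, each = length(field$depth)),
                   depth_m = rep(field$depth, length(field$axis)),
                   u_ms = as.vector(field$u), v_ms = as.vector(field$v),
                   provenance = field$provenance)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_velocity_csv
#' @export
read_velocity_csv <- function(path) {
  df <- utils::read.csv(path)
  depth <- sort(unique(df$depth_m))
  axis <- sort(unique(df$axis))
  o <- order(df$axis, df$depth_m)
  velocity_field(depth, axis,
                 u = matrix(df$u_ms[o], length(depth), length(axis)),
                 v = matrix(df$v_ms[o], length(depth), length(axis)),
                 provenance = df$provenance[1])
}

#' Read and write seasonal climatologies as CSV
#'
#' @param clim a [seasonal_climatology()]
#' @param path CSV file path
#' @return the written path / the reconstructed object
#' @export
write_climatology_csv <- function(clim, path) {
  utils::write.csv(as.data.frame(clim), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climatology_csv
#' @export
read_climatology_csv <- function(path) {
  df <- utils::read.csv(path)
  out <- seasonal_climatology(df$phase, df$value, df$se, df$n_effective)
  extra <- setdiff(names(df), names(out))
  for (nm in extra) out[[nm]] <- df[[nm]]
  out
}

#' Write a ground-truth record or run manifest as JSON
#'
#' @param x a list (functions are dropped; matrices become nested arrays)
#' @param path JSON file path
#' @return the written path / the parsed list
#' @export
write_truth_json <- function(x, path) {
  drop_funs <- function(l) {
    if (!is.list(l)) return(l)
    l <- l[!vapply(l, is.function, logical(1))]
    lapply(l, drop_funs)
  }
  jsonlite::write_json(drop_funs(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# md5 of a serialized R object (config hash for run manifests)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2)
  unname(tools::md5sum(f))
}

run_manifest <- function(config, seed) {
  list(package = "equaflux",
       version = as.character(utils::packageVersion("equaflux")),
       seed = seed,
       config_hash = config_hash(config),
       r_version = R.version.string)
}
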