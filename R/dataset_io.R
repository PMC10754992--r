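#' Write a spike dataset to CSV with a JSON manifest
#'
#' The CSV has header `sample_id,label,source,n_spikes,t_001,...,t_<L_max>`
#' with times in ms at 0.001-ms resolution and explicit zero padding. A
#' sidecar manifest `<path>.manifest.json` carries `T_max`, `L_max`,
#' generator name, parameters, seed and class counts, so
#' `read_dataset(write_dataset(ds))` is the identity on every field.
#'
#' @param ds a `spike_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "spike_dataset"))
  tm <- round(ds$times, 3)
  dt <- data.table::data.table(sample_id = ds$sample_id, label = ds$label,
                               source = ds$source,
                               n_spikes = rowSums(tm != 0))
  tcols <- data.table::as.data.table(tm)
  data.table::setnames(tcols, sprintf("t_%03d", seq_len(ds$L_max)))
  data.table::fwrite(cbind(dt, tcols), path)
  manifest <- list(T_max = ds$T_max, L_max = ds$L_max,
                   generator = ds$provenance$generator %||% "unknown",
                   params = ds$provenance$params,
                   seed = ds$provenance$seed,
                   class_counts = as.list(class_counts(ds)),
                   provenance = ds$provenance[setdiff(names(ds$provenance),
                                                      c("generator", "params", "seed"))])
  jsonlite::write_json(manifest, manifest_path(path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

manifest_path <- function(path) paste0(sub("\\.csv$", "", path), ".manifest.json")

#' Read a spike dataset written by [write_dataset()]
#'
#' Enforces the dataset invariants: all nonzero times in `(0, T_max]`,
#' padding zeros trailing. A non-increasing nonzero prefix is legal for
#' `source = "file"` rows (noise-perturbed data keep their original entry
#' order) and raises a warning; for generator sources it is an error.
#' Violations are reported with the offending row and column.
#'
#' @param path CSV path written by [write_dataset()].
#' @return a `spike_dataset`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  mpath <- manifest_path(path)
  if (!file.exists(mpath)) stop("missing manifest: ", mpath)
  man <- jsonlite::read_json(mpath, simplifyVector = TRUE)
  dt <- data.table::fread(path, data.table = FALSE)
  need <- c("sample_id", "label", "source", "n_spikes")
  if (!all(need %in% names(dt)))
    stop("malformed dataset file: missing column(s) ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  tcols <- grep("^t_\\d+$", names(dt), value = TRUE)
  if (length(tcols) != man$L_max)
    stop(sprintf("malformed dataset file: %d time columns, manifest L_max = %d",
                 length(tcols), man$L_max))
  tm <- as.matrix(dt[, tcols])
  dimnames(tm) <- NULL
  for (i in seq_len(nrow(tm))) {
    nz <- which(tm[i, ] != 0)
    if (length(nz) == 0) next
    bad <- nz[tm[i, nz] < 0 | tm[i, nz] > man$T_max]
    if (length(bad))
      stop(sprintf("parse error at row %d, column %s: spike time %g outside (0, %g]",
                   i, tcols[bad[1]], tm[i, bad[1]], man$T_max))
    if (max(nz) != length(nz))
      stop(sprintf("parse error at row %d, column %s: padding zero precedes a spike",
                   i, tcols[setdiff(seq_len(max(nz)), nz)[1]]))
    if (dt$n_spikes[i] != length(nz))
      stop(sprintf("parse error at row %d: n_spikes = %d but %d nonzero times",
                   i, dt$n_spikes[i], length(nz)))
    if (length(nz) > 1 && any(diff(tm[i, nz]) <= 0)) {
      if (identical(dt$source[i], "file")) {
        warning(sprintf("row %d: non-increasing spike times (noise-perturbed data)", i),
                call. = FALSE)
      } else {
        stop(sprintf("parse error at row %d: non-increasing spike times for source '%s'",
                     i, dt$source[i]))
      }
    }
  }
  prov <- c(list(generator = man$generator, params = man$params,
                 seed = if (!is.null(man$seed)) as.numeric(man$seed)),
            as.list(man$provenance))
  new_spike_dataset(tm, dt$label, dt$sample_id, dt$source,
                    as.numeric(man$T_max), as.integer(man$L_max), prov)
}
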