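#' Load and validate a cultivator configuration file
#'
#' Reads a YAML or JSON configuration (by file extension) describing the two
#' species and the cultivator, validates it against the expected schema
#' (unknown keys are rejected, constraints reported by key name), and
#' returns a ready [competition_model()].
#'
#' Expected structure:
#' \preformatted{
#' species:
#'   - {name, mu_max, k_e, shade, od680, aq}
#'   - {name, mu_max, k_e, shade, od680, aq}
#' cultivator: {e0, mode, c_set | d, light_model}
#' seed: 0          # optional
#' }
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [competition_model()] with attribute `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension \".", ext, "\" (yaml/yml/json)",
         call. = FALSE))
  allowed_top <- c("species", "cultivator", "seed")
  unknown <- setdiff(names(raw), allowed_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (is.null(raw$species) || length(raw$species) != 2L) {
    # jsonlite may simplify a homogeneous species array to a data.frame
    if (is.data.frame(raw$species) && nrow(raw$species) == 2L)
      raw$species <- lapply(seq_len(2), function(i) as.list(raw$species[i, ]))
    else
      stop("config must define exactly 2 entries under `species`",
           call. = FALSE)
  }
  sp_keys <- c("name", "mu_max", "k_e", "shade", "od680", "aq")
  species <- lapply(raw$species, function(s) {
    bad <- setdiff(names(s), sp_keys)
    if (length(bad))
      stop("unknown species key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    miss <- setdiff(c("name", "mu_max", "k_e", "shade"), names(s))
    if (length(miss))
      stop("species entry missing key(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    alga_species(s$name, s$mu_max, s$k_e, s$shade,
                 od680 = s$od680 %||% 1, aq = s$aq %||% NA_real_)
  })
  cv <- raw$cultivator
  if (is.null(cv)) stop("config missing `cultivator` section", call. = FALSE)
  cv_keys <- c("e0", "c_set", "d", "mode", "light_model")
  bad <- setdiff(names(cv), cv_keys)
  if (length(bad))
    stop("unknown cultivator key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- cultivator(e0 = cv$e0, c_set = cv$c_set, d = cv$d,
                    mode = cv$mode %||% "turbidostat",
                    light_model = cv$light_model %||% "linearized")
  m <- competition_model(species[[1]], species[[2]], cfg)
  attr(m, "seed") <- as.integer(raw$seed %||% 0L)
  m
}
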