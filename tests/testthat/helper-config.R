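# Shared fixtures: the base-case configuration is immutable, so load it once.
.base_cfg_env <- new.env()

base_cfg <- function() {
  if (is.null(.base_cfg_env$cfg)) .base_cfg_env$cfg <- load_config()
  .base_cfg_env$cfg
}

# Write a copy of the base-case YAML with a textual tweak applied, next to the
# data CSVs, and return its path.
tweaked_config_path <- function(transform) {
  lines <- readLines(base_case_path())
  lines <- transform(lines)
  dir <- file.path(tempfile("cfg"), "x")
  dir.create(dir, recursive = TRUE)
  for (f in c("service_catalog.csv", "inpatient_groups.csv")) {
    file.copy(system.file("extdata", f, package = "preecon"), file.path(dir, f))
  }
  path <- file.path(dir, "config.yaml")
  writeLines(lines, path)
  path
}

# Binomial standard error for a proportion.
binom_se <- function(p, n) sqrt(p * (1 - p) / n)
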