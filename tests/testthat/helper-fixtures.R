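# Shared fixture builders; everything is generated in code.

make_compounds <- function(smiles, labels, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("c%02d", seq_along(smiles))
  compound_set(data.frame(id = ids, smiles = smiles, label = labels),
               quiet = TRUE)
}

# two-class data with the class signal planted on the first feature
# (d-prime 4 on that axis), remaining features pure noise
make_clouds <- function(n_per_class = 100, p_noise = 4, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- cbind(matrix(rnorm(n * p_noise), n, p_noise))
  x <- cbind(sig = rnorm(n) + rep(c(0, 4), each = n_per_class), x)
  colnames(x) <- c("sig", paste0("noise", seq_len(p_noise)))
  list(x = x, y = rep(c("inactive", "active"), each = n_per_class))
}

make_herb_df <- function(name, natures = "", flavors = "", channels = "",
                         status = "hepatoprotective", category = "antipyretics") {
  data.frame(name = name, category = category, natures = natures,
             flavors = flavors, channels = channels, status = status)
}

tmp_file <- function(lines, ext = ".csv") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
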