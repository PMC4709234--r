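# Document readers/writers: GEXF property graphs and the CSV pattern
# dialect. All fixtures are generated in code and written to tempfiles.

test_that("a minimal three-node GEXF circuit loads as a one-port spec", {
  spec <- lpuSpec(
    "mini", interfaceTable(outSpike = "/mini/o[0]"),
    components = data.frame(component = c("n1", "s1"),
                            model = c("LeakyIAF", "AlphaSynapse"),
                            params = I(list(numeric(0), c(tau = 3))),
                            stringsAsFactors = FALSE),
    edges = data.frame(from = "n1", to = "s1", stringsAsFactors = FALSE),
    bindings = data.frame(port = "/mini/o[0]", component = "n1",
                          stringsAsFactors = FALSE))
  f <- withr::local_tempfile(fileext = ".gexf")
  writeLpuGexf(spec, f)
  got <- readLpuGexf(f)
  expect_identical(got@id, "mini")
  expect_identical(nrow(got@interface), 1L)
  expect_identical(got@interface$transmission, "spike")
  expect_identical(got@interface$io, "out")
  expect_identical(sort(got@components$component), c("n1", "s1"))
  expect_equal(got@components$params[[match("s1", got@components$component)]],
               c(tau = 3))
})

test_that("LPU GEXF round-trips structurally", {
  fx <- buildRetinaLamina(rings = 0)  # 1 ommatidium keeps the file tiny
  for (spec in list(fx$retina, fx$lamina)) {
    f <- withr::local_tempfile(fileext = ".gexf")
    writeLpuGexf(spec, f)
    got <- readLpuGexf(f)
    expect_identical(got@id, spec@id)
    expect_identical(
      got@interface[order(got@interface$identifier), ],
      spec@interface[order(spec@interface$identifier), ],
      ignore_attr = TRUE)
    expect_setequal(got@components$component, spec@components$component)
    expect_setequal(paste(got@edges$from, got@edges$to),
                    paste(spec@edges$from, spec@edges$to))
    expect_setequal(paste(got@bindings$port, got@bindings$component),
                    paste(spec@bindings$port, spec@bindings$component))
    expect_identical(nrow(validateSpec(got)), 0L)
  }
})

test_that("GEXF schema violations carry node-level diagnostics", {
  f <- withr::local_tempfile(fileext = ".gexf")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '<graph defaultedgetype="directed" label="bad">',
    '<attributes class="node">',
    '<attribute id="0" title="model" type="string"/>',
    '</attributes>',
    '<nodes><node id="mystery"><attvalues>',
    '<attvalue for="0" value="NoSuchModel"/>',
    '</attvalues></node></nodes>',
    '<edges/></graph></gexf>'), f)
  expect_error(readLpuGexf(f), class = "unknownModelError")
  f2 <- withr::local_tempfile(fileext = ".gexf")
  writeLines(c(
    '<?xml version="1.0"?>',
    '<gexf xmlns="http://www.gexf.net/1.2draft" version="1.2">',
    '<graph defaultedgetype="directed" label="bad">',
    '<nodes><node id="orphan"/></nodes>',
    '<edges/></graph></gexf>'), f2)
  err <- expect_error(readLpuGexf(f2), class = "documentError")
  expect_match(conditionMessage(err), "orphan")
})

test_that("the worked-example pattern round-trips through CSV", {
  p <- workedPattern()
  cf <- withr::local_tempfile(fileext = ".csv")
  pf <- withr::local_tempfile(fileext = ".csv")
  writePatternCsv(p, cf, pf)
  got <- readPatternCsv(cf, pf)
  expect_identical(connectionCount(got), 6L)
  expect_identical(nrow(ports(got)), 11L)
  expect_identical(ports(got)[order(ports(got)$identifier), ],
                   ports(p)[order(ports(p)$identifier), ],
                   ignore_attr = TRUE)
  expect_setequal(paste(connections(got)$source, connections(got)$destination),
                  paste(connections(p)$source, connections(p)$destination))
})

test_that("file-level violations are located by row", {
  p <- workedPattern()
  cf <- withr::local_tempfile(fileext = ".csv")
  pf <- withr::local_tempfile(fileext = ".csv")
  writePatternCsv(p, cf, pf)
  # duplicate destination: fan-in at a named row
  kon <- utils::read.csv(cf, colClasses = "character")
  kon <- rbind(kon[1, ], kon)
  kon$source[2] <- "/lam[1]"
  utils::write.csv(kon, cf, row.names = FALSE, quote = FALSE)
  err <- expect_error(readPatternCsv(cf, pf), class = "fanInError")
  expect_match(conditionMessage(err), "row 2")
  # transmission mismatch located by row
  writePatternCsv(p, cf, pf)
  kon <- utils::read.csv(cf, colClasses = "character")
  kon$destination[1] <- "/med[3]"  # gpot source -> spike destination
  utils::write.csv(kon, cf, row.names = FALSE, quote = FALSE)
  expect_error(readPatternCsv(cf, pf), class = "typeMismatchError")
  # malformed identifier
  writePatternCsv(p, cf, pf)
  pts <- utils::read.csv(pf, colClasses = "character")
  pts$identifier[1] <- "/lam[0:"
  utils::write.csv(pts, pf, row.names = FALSE, quote = FALSE)
  expect_error(readPatternCsv(cf, pf), class = "documentError")
})

test_that("an empty connection table with attributes is a valid pattern", {
  p <- makePattern("/a[0:2]", "/b[0:2]")
  p <- setPortAttributes(p, "/a[0:2]", 0, "in", "gpot")
  p <- setPortAttributes(p, "/b[0:2]", 1, "out", "gpot")
  cf <- withr::local_tempfile(fileext = ".csv")
  pf <- withr::local_tempfile(fileext = ".csv")
  writePatternCsv(p, cf, pf)
  got <- readPatternCsv(cf, pf)
  expect_identical(connectionCount(got), 0L)
  expect_true(validObject(got))
})

test_that("randomized valid patterns survive CSV and GEXF round trips", {
  set.seed(71)
  for (rep in 1:8) {
    n0 <- sample(2:6, 1); n1 <- sample(2:6, 1)
    p <- makePattern(sprintf("/u[0:%d]", n0), sprintf("/v[0:%d]", n1))
    kind <- sample(c("gpot", "spike"), 1)
    p <- setPortAttributes(p, sprintf("/u[0:%d]", n0), 0, "in", kind)
    p <- setPortAttributes(p, sprintf("/v[0:%d]", n1), 1, "out", kind)
    ndst <- sample(n1, 1)
    dsts <- sample(n1, ndst) - 1
    srcs <- sample(n0, ndst, replace = TRUE) - 1
    if (ndst > 0)
      p <- addConnections(p, sprintf("/u[%d]", srcs), sprintf("/v[%d]", dsts))
    cf <- withr::local_tempfile(); pf <- withr::local_tempfile()
    writePatternCsv(p, cf, pf)
    gotCsv <- readPatternCsv(cf, pf)
    gf <- withr::local_tempfile(fileext = ".gexf")
    writePatternGexf(p, gf)
    gotGexf <- readPatternGexf(gf)
    for (got in list(gotCsv, gotGexf)) {
      expect_identical(ports(got)[order(ports(got)$identifier), ],
                       ports(p)[order(ports(p)$identifier), ],
                       ignore_attr = TRUE)
      expect_setequal(
        paste(connections(got)$source, connections(got)$destination),
        paste(connections(p)$source, connections(p)$destination))
    }
  }
})
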