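#include <Rcpp.h>

#include <cmath>
#include <cstdio>
#include <cstring>
#include <fstream>

#include "busz_core.h"

using namespace Rcpp;
using namespace busz;

// ------------------------------------------------------------ conversions
// R numerics carry integers exactly up to 2^53; the numeric codec APIs
// enforce that bound.  Full 64-bit values never cross the R boundary as
// numbers: they travel as nucleotide strings or stay inside the C++ file
// pipeline.
static const double kMaxExact = 9007199254740992.0;  // 2^53

static uint64_t asU64(double x, const char* what) {
  if (!R_finite(x) || x < 0 || x != std::floor(x))
    throw busz_error(std::string("domain: ") + what +
                     " must be a non-negative integer");
  if (x > kMaxExact)
    throw busz_error(std::string("domain: ") + what +
                     " exceeds 2^53 and is not exactly representable");
  return (uint64_t)x;
}

static std::vector<uint64_t> asU64Vec(const NumericVector& x,
                                      const char* what) {
  std::vector<uint64_t> out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i) out[i] = asU64(x[i], what);
  return out;
}

static NumericVector asNumeric(const std::vector<uint64_t>& x,
                               const char* what) {
  NumericVector out(x.size());
  for (size_t i = 0; i < x.size(); ++i) {
    if (x[i] > (uint64_t)kMaxExact)
      throw busz_error(std::string("domain: decoded ") + what +
                       " exceeds 2^53 and is not exactly representable");
    out[i] = (double)x[i];
  }
  return out;
}

static List bitsOut(const BitWriter& bw) {
  RawVector bytes(bw.bytes.size());
  std::copy(bw.bytes.begin(), bw.bytes.end(), bytes.begin());
  return List::create(_["bytes"] = bytes, _["nbits"] = (double)bw.nbits);
}

static BitReader bitsIn(const RawVector& bytes, double nbits) {
  const uint64_t nb = asU64(nbits, "nbits");
  if (nb > (uint64_t)bytes.size() * 8)
    throw busz_error("domain: nbits exceeds the buffer length");
  return BitReader(RAW(bytes), nb);
}

// -------------------------------------------------------------- sequences

// [[Rcpp::export]]
NumericVector cpp_encode_sequence(CharacterVector seqs) {
  NumericVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const uint64_t code = encodeSeq(as<std::string>(seqs[i]));
    out[i] = (double)code;
    if (code > (uint64_t)kMaxExact)
      Rf_warning("2-bit code exceeds 2^53; the returned numeric is inexact");
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_decode_sequence(NumericVector codes, int len) {
  CharacterVector out(codes.size());
  for (R_xlen_t i = 0; i < codes.size(); ++i)
    out[i] = decodeSeq(asU64(codes[i], "code"), (unsigned)len);
  return out;
}

// exact round trip for any length <= 32, entirely in C++
// [[Rcpp::export]]
CharacterVector cpp_sequence_roundtrip(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (R_xlen_t i = 0; i < seqs.size(); ++i) {
    const std::string s = as<std::string>(seqs[i]);
    out[i] = decodeSeq(encodeSeq(s), (unsigned)s.size());
  }
  return out;
}

// --------------------------------------------------------------- bit pack

// [[Rcpp::export]]
List cpp_pack_bits(NumericVector values, IntegerVector widths,
                   bool align = false) {
  if (values.size() != widths.size())
    stop("values and widths must have equal length");
  BitWriter bw;
  for (R_xlen_t i = 0; i < values.size(); ++i) {
    if (widths[i] < 0 || widths[i] > 64)
      throw busz_error("domain: bit width must be in 0..64");
    bw.writeBits(asU64(values[i], "value"), (unsigned)widths[i]);
  }
  if (align) bw.alignToByte();
  return bitsOut(bw);
}

// [[Rcpp::export]]
NumericVector cpp_unpack_bits(RawVector bytes, double nbits,
                              IntegerVector widths) {
  BitReader br = bitsIn(bytes, nbits);
  std::vector<uint64_t> out(widths.size());
  for (R_xlen_t i = 0; i < widths.size(); ++i) {
    if (widths[i] < 0 || widths[i] > 64)
      throw busz_error("domain: bit width must be in 0..64");
    out[i] = br.readBits((unsigned)widths[i]);
  }
  return asNumeric(out, "value");
}

// --------------------------------------------------------------- fibonacci

// [[Rcpp::export]]
List cpp_fib_encode(NumericVector values) {
  BitWriter bw;
  for (R_xlen_t i = 0; i < values.size(); ++i) {
    const uint64_t v = asU64(values[i], "value");
    if (v == 0) throw busz_error("domain: Fibonacci coding requires n >= 1");
    fibEncode((u128)v, bw);
  }
  return bitsOut(bw);
}

// [[Rcpp::export]]
NumericVector cpp_fib_decode(RawVector bytes, double nbits, double n) {
  BitReader br = bitsIn(bytes, nbits);
  std::vector<uint64_t> out;
  if (n < 0) {
    while (br.remaining() > 0) out.push_back((uint64_t)fibDecode(br));
  } else {
    const uint64_t k = asU64(n, "n");
    for (uint64_t i = 0; i < k; ++i) out.push_back((uint64_t)fibDecode(br));
  }
  return asNumeric(out, "value");
}

// -------------------------------------------------------------------- FRLE

// [[Rcpp::export]]
List cpp_frle0_encode(NumericVector values) {
  BitWriter bw;
  frle0Encode(asU64Vec(values, "value"), bw);
  return bitsOut(bw);
}

// [[Rcpp::export]]
NumericVector cpp_frle0_decode(RawVector bytes, double nbits, double n) {
  BitReader br = bitsIn(bytes, nbits);
  return asNumeric(frle0Decode(br, asU64(n, "n")), "value");
}

// [[Rcpp::export]]
List cpp_frle1_encode(NumericVector values) {
  BitWriter bw;
  frle1Encode(asU64Vec(values, "value"), bw);
  return bitsOut(bw);
}

// [[Rcpp::export]]
NumericVector cpp_frle1_decode(RawVector bytes, double nbits, double n) {
  BitReader br = bitsIn(bytes, nbits);
  return asNumeric(frle1Decode(br, asU64(n, "n")), "value");
}

// ------------------------------------------------------------------ deltas

// [[Rcpp::export]]
NumericVector cpp_delta_barcodes(NumericVector bc) {
  return asNumeric(deltaBarcodes(asU64Vec(bc, "barcode")), "delta");
}

// [[Rcpp::export]]
NumericVector cpp_undelta_barcodes(NumericVector d) {
  return asNumeric(undeltaBarcodes(asU64Vec(d, "delta")), "barcode");
}

// [[Rcpp::export]]
NumericVector cpp_delta_umis(NumericVector umi, NumericVector bc) {
  return asNumeric(
      deltaUmis(asU64Vec(umi, "umi"), asU64Vec(bc, "barcode")), "delta");
}

// [[Rcpp::export]]
NumericVector cpp_undelta_umis(NumericVector d, NumericVector bc) {
  return asNumeric(
      undeltaUmis(asU64Vec(d, "delta"), asU64Vec(bc, "barcode")), "umi");
}

// ------------------------------------------------------------------ NewPFD

// [[Rcpp::export]]
List cpp_newpfd_encode(NumericVector values, double nPfd, double f) {
  BitWriter bw;
  std::vector<NewpfdSubblock> plan;
  newpfdEncode(asU64Vec(values, "value"), asU64(nPfd, "nPfd"), f, bw, &plan);
  NumericVector k(plan.size()), b(plan.size()), nv(plan.size()),
      ne(plan.size());
  for (size_t i = 0; i < plan.size(); ++i) {
    k[i] = (double)plan[i].k;
    b[i] = (double)plan[i].b;
    nv[i] = (double)plan[i].nValues;
    ne[i] = (double)plan[i].nExceptions;
  }
  List out = bitsOut(bw);
  out["plan"] = DataFrame::create(_["k"] = k, _["b"] = b, _["nValues"] = nv,
                                  _["nExceptions"] = ne);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_newpfd_decode(RawVector bytes, double nbits, double n,
                                double nPfd) {
  BitReader br = bitsIn(bytes, nbits);
  return asNumeric(newpfdDecode(br, asU64(n, "n"), asU64(nPfd, "nPfd")),
                   "value");
}

// ----------------------------------------------------------------- file IO

static void wU32(std::ostream& os, uint32_t v) {
  uint8_t b[4] = {(uint8_t)(v & 0xff), (uint8_t)((v >> 8) & 0xff),
                  (uint8_t)((v >> 16) & 0xff), (uint8_t)((v >> 24) & 0xff)};
  os.write((const char*)b, 4);
}

static void wU64(std::ostream& os, uint64_t v) {
  wU32(os, (uint32_t)(v & 0xffffffffu));
  wU32(os, (uint32_t)(v >> 32));
}

static bool rU32(std::istream& is, uint32_t& v) {
  uint8_t b[4];
  is.read((char*)b, 4);
  if (is.gcount() != 4) return false;
  v = (uint32_t)b[0] | ((uint32_t)b[1] << 8) | ((uint32_t)b[2] << 16) |
      ((uint32_t)b[3] << 24);
  return true;
}

static bool rU64(std::istream& is, uint64_t& v) {
  uint32_t lo, hi;
  if (!rU32(is, lo) || !rU32(is, hi)) return false;
  v = (uint64_t)lo | ((uint64_t)hi << 32);
  return true;
}

static const char kBusMagic[4] = {'B', 'U', 'S', '\0'};
static const char kBuszMagic[8] = {'B', 'U', 'S', 'Z', '0', '0', '0', '1'};
static const char kIdxMagic[8] = {'B', 'U', 'S', 'Z', 'I', 'D', 'X', '1'};

static void writeBusHeader(std::ostream& os, const BusHeader& h) {
  os.write(kBusMagic, 4);
  wU32(os, h.version);
  wU32(os, h.bcLen);
  wU32(os, h.umiLen);
  wU32(os, (uint32_t)h.text.size());
  os.write(h.text.data(), h.text.size());
}

static BusHeader readBusHeader(std::istream& is) {
  char magic[4];
  is.read(magic, 4);
  if (is.gcount() != 4 || std::memcmp(magic, kBusMagic, 4) != 0)
    throw busz_error("format: not a BUS file (bad magic)");
  BusHeader h;
  uint32_t tlen;
  if (!rU32(is, h.version) || !rU32(is, h.bcLen) || !rU32(is, h.umiLen) ||
      !rU32(is, tlen))
    throw busz_error("truncated: BUS header is incomplete");
  if (h.bcLen < 1 || h.bcLen > 32 || h.umiLen < 1 || h.umiLen > 32)
    throw busz_error("format: barcode/UMI length must be in 1..32");
  h.text.resize(tlen);
  is.read(&h.text[0], tlen);
  if ((uint32_t)is.gcount() != tlen)
    throw busz_error("truncated: BUS header text is incomplete");
  return h;
}

static size_t busHeaderSize(const BusHeader& h) { return 20 + h.text.size(); }

// one 32-byte record: u64 barcode, u64 umi, i32 ec, u32 count, u32 flags,
// u32 zero padding — all little-endian
static void writeRecord(std::ostream& os, const BusRecord& r) {
  wU64(os, r.barcode);
  wU64(os, r.umi);
  wU32(os, (uint32_t)r.ec);
  wU32(os, r.count);
  wU32(os, r.flags);
  wU32(os, 0);
}

static bool readRecord(std::istream& is, BusRecord& r, uint32_t& padding) {
  uint8_t buf[32];
  is.read((char*)buf, 32);
  const std::streamsize got = is.gcount();
  if (got == 0) return false;
  if (got != 32)
    throw busz_error("truncated: BUS payload is not a multiple of 32 bytes");
  auto u32 = [&](int off) {
    return (uint32_t)buf[off] | ((uint32_t)buf[off + 1] << 8) |
           ((uint32_t)buf[off + 2] << 16) | ((uint32_t)buf[off + 3] << 24);
  };
  auto u64 = [&](int off) {
    return (uint64_t)u32(off) | ((uint64_t)u32(off + 4) << 32);
  };
  r = {u64(0), u64(8), (int32_t)u32(16), u32(20), u32(24)};
  padding = u32(28);
  return true;
}

static std::ifstream openIn(const std::string& path) {
  std::ifstream is(path, std::ios::binary);
  if (!is) throw busz_error("io: cannot open '" + path + "' for reading");
  return is;
}

static std::ofstream openOut(const std::string& path) {
  std::ofstream os(path, std::ios::binary);
  if (!os) throw busz_error("io: cannot open '" + path + "' for writing");
  return os;
}

static double fileSize(const std::string& path) {
  std::ifstream is(path, std::ios::binary | std::ios::ate);
  if (!is) throw busz_error("io: cannot open '" + path + "'");
  return (double)is.tellg();
}

// ----------------------------------------------------------- BUS read/write

static List recordsToR(const std::vector<BusRecord>& recs,
                       const BusHeader& h) {
  const size_t n = recs.size();
  CharacterVector bc(n), umi(n);
  NumericVector ec(n), cnt(n), flg(n);
  for (size_t i = 0; i < n; ++i) {
    bc[i] = decodeSeq(recs[i].barcode, h.bcLen);
    umi[i] = decodeSeq(recs[i].umi, h.umiLen);
    ec[i] = (double)recs[i].ec;
    cnt[i] = (double)recs[i].count;
    flg[i] = (double)recs[i].flags;
  }
  return List::create(_["barcode"] = bc, _["umi"] = umi, _["ec"] = ec,
                      _["count"] = cnt, _["flags"] = flg);
}

static std::vector<BusRecord> recordsFromR(CharacterVector bc,
                                           CharacterVector umi,
                                           NumericVector ec, NumericVector cnt,
                                           NumericVector flg, uint32_t bcLen,
                                           uint32_t umiLen) {
  const R_xlen_t n = bc.size();
  if (umi.size() != n || ec.size() != n || cnt.size() != n || flg.size() != n)
    throw busz_error("domain: record columns differ in length");
  std::vector<BusRecord> recs(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const std::string b = as<std::string>(bc[i]);
    const std::string u = as<std::string>(umi[i]);
    if (b.size() != bcLen)
      throw busz_error("domain: barcode length mismatch at record " +
                       std::to_string(i + 1));
    if (u.size() != umiLen)
      throw busz_error("domain: UMI length mismatch at record " +
                       std::to_string(i + 1));
    const double e = ec[i];
    if (!R_finite(e) || e != std::floor(e) || e < INT32_MIN || e > INT32_MAX)
      throw busz_error("domain: EC out of 32-bit signed range at record " +
                       std::to_string(i + 1));
    const double c = cnt[i], fl = flg[i];
    if (!R_finite(c) || c != std::floor(c) || c < 0 || c > UINT32_MAX)
      throw busz_error("domain: count out of 32-bit range at record " +
                       std::to_string(i + 1));
    if (!R_finite(fl) || fl != std::floor(fl) || fl < 0 || fl > UINT32_MAX)
      throw busz_error("domain: flags out of 32-bit range at record " +
                       std::to_string(i + 1));
    recs[i] = {encodeSeq(b), encodeSeq(u), (int32_t)e, (uint32_t)c,
               (uint32_t)fl};
  }
  return recs;
}

// [[Rcpp::export]]
List cpp_read_bus(std::string path) {
  std::ifstream is = openIn(path);
  const BusHeader h = readBusHeader(is);
  std::vector<BusRecord> recs;
  uint64_t nonzeroPad = 0;
  BusRecord r;
  uint32_t pad;
  while (readRecord(is, r, pad)) {
    if (pad != 0) ++nonzeroPad;
    recs.push_back(r);
  }
  List rec = recordsToR(recs, h);
  return List::create(_["version"] = (double)h.version,
                      _["bcLen"] = (int)h.bcLen, _["umiLen"] = (int)h.umiLen,
                      _["text"] = h.text, _["records"] = rec,
                      _["nonzeroPadding"] = (double)nonzeroPad);
}

// [[Rcpp::export]]
double cpp_write_bus(std::string path, double version, int bcLen, int umiLen,
                     std::string text, CharacterVector bc, CharacterVector umi,
                     NumericVector ec, NumericVector cnt, NumericVector flg) {
  BusHeader h{(uint32_t)version, (uint32_t)bcLen, (uint32_t)umiLen, text};
  if (h.bcLen < 1 || h.bcLen > 32 || h.umiLen < 1 || h.umiLen > 32)
    throw busz_error("format: barcode/UMI length must be in 1..32");
  std::vector<BusRecord> recs =
      recordsFromR(bc, umi, ec, cnt, flg, h.bcLen, h.umiLen);
  std::ofstream os = openOut(path);
  writeBusHeader(os, h);
  for (const BusRecord& r : recs) writeRecord(os, r);
  os.flush();
  if (!os) throw busz_error("io: write failed for '" + path + "'");
  return (double)(busHeaderSize(h) + 32.0 * recs.size());
}

// ------------------------------------------------------------- sort & merge

static bool keyLess(const BusRecord& a, const BusRecord& b) {
  if (a.barcode != b.barcode) return a.barcode < b.barcode;
  if (a.umi != b.umi) return a.umi < b.umi;
  return a.ec < b.ec;
}

// [[Rcpp::export]]
List cpp_sort_merge(CharacterVector bc, CharacterVector umi, NumericVector ec,
                    NumericVector cnt, NumericVector flg, int bcLen,
                    int umiLen) {
  std::vector<BusRecord> recs =
      recordsFromR(bc, umi, ec, cnt, flg, (uint32_t)bcLen, (uint32_t)umiLen);
  std::stable_sort(recs.begin(), recs.end(), keyLess);
  std::vector<BusRecord> out;
  out.reserve(recs.size());
  for (const BusRecord& r : recs) {
    if (!out.empty() && out.back().barcode == r.barcode &&
        out.back().umi == r.umi && out.back().ec == r.ec) {
      const uint64_t sum = (uint64_t)out.back().count + r.count;
      if (sum > UINT32_MAX)
        throw busz_error("domain: merged count exceeds 32-bit range");
      out.back().count = (uint32_t)sum;
      out.back().flags |= r.flags;
    } else {
      out.push_back(r);
    }
  }
  BusHeader h{1, (uint32_t)bcLen, (uint32_t)umiLen, ""};
  return recordsToR(out, h);
}

// ------------------------------------------------------------ block wrappers

// [[Rcpp::export]]
RawVector cpp_compress_block(CharacterVector bc, CharacterVector umi,
                             NumericVector ec, NumericVector cnt,
                             NumericVector flg, int bcLen, int umiLen,
                             double nPfd, double f) {
  std::vector<BusRecord> recs =
      recordsFromR(bc, umi, ec, cnt, flg, (uint32_t)bcLen, (uint32_t)umiLen);
  BuszParams p{recs.size() ? recs.size() : 1, asU64(nPfd, "nPfd"), f};
  std::vector<uint8_t> payload = compressBlock(recs, p);
  RawVector out(payload.size());
  std::copy(payload.begin(), payload.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
List cpp_decompress_block(RawVector payload, double n, int bcLen, int umiLen,
                          double nPfd, double f) {
  std::vector<uint8_t> bytes(payload.begin(), payload.end());
  BuszParams p{asU64(n, "n"), asU64(nPfd, "nPfd"), f};
  std::vector<BusRecord> recs = decompressBlock(bytes, p.blockSize, p);
  BusHeader h{1, (uint32_t)bcLen, (uint32_t)umiLen, ""};
  return recordsToR(recs, h);
}

// ---------------------------------------------------------------- container

struct BuszHeaderFull {
  BusHeader bus;
  uint64_t blockSize;
  uint64_t nPfd;
  uint32_t fPpt;  // fraction f in parts per thousand
};

static void writeBuszHeader(std::ostream& os, const BuszHeaderFull& h) {
  os.write(kBuszMagic, 8);
  wU32(os, h.bus.version);
  wU32(os, h.bus.bcLen);
  wU32(os, h.bus.umiLen);
  wU32(os, (uint32_t)h.bus.text.size());
  os.write(h.bus.text.data(), h.bus.text.size());
  wU32(os, (uint32_t)h.blockSize);
  wU32(os, (uint32_t)h.nPfd);
  wU32(os, h.fPpt);
}

static BuszHeaderFull readBuszHeader(std::istream& is) {
  char magic[8];
  is.read(magic, 8);
  if (is.gcount() != 8)
    throw busz_error("format: not a BUSZ file (file too short)");
  if (std::memcmp(magic, kBusMagic, 4) == 0 &&
      std::memcmp(magic, kBuszMagic, 8) != 0)
    throw busz_error("format: not a BUSZ file (plain BUS input?)");
  if (std::memcmp(magic, kBuszMagic, 8) != 0)
    throw busz_error("format: not a BUSZ file (bad magic)");
  BuszHeaderFull h;
  uint32_t tlen, bs, np;
  if (!rU32(is, h.bus.version) || !rU32(is, h.bus.bcLen) ||
      !rU32(is, h.bus.umiLen) || !rU32(is, tlen))
    throw busz_error("truncated: BUSZ header is incomplete");
  h.bus.text.resize(tlen);
  is.read(&h.bus.text[0], tlen);
  if ((uint32_t)is.gcount() != tlen)
    throw busz_error("truncated: BUSZ header text is incomplete");
  if (!rU32(is, bs) || !rU32(is, np) || !rU32(is, h.fPpt))
    throw busz_error("truncated: BUSZ header is incomplete");
  h.blockSize = bs;
  h.nPfd = np;
  if (h.blockSize < 1 || h.nPfd < 1)
    throw busz_error("format: invalid BUSZ compression parameters");
  return h;
}

static size_t buszHeaderSize(const BuszHeaderFull& h) {
  return 8 + 16 + h.bus.text.size() + 12;
}

// [[Rcpp::export]]
List cpp_compress_file(std::string input, std::string output, double blockSize,
                       double nPfd, double f, bool writeIndex,
                       std::string indexPath) {
  const uint64_t bs = asU64(blockSize, "blockSize");
  if (bs < 1 || bs > UINT32_MAX)
    throw busz_error("domain: blockSize must be in 1..2^32-1");
  const uint64_t np = asU64(nPfd, "nPfd");
  if (np < 1 || np > UINT32_MAX)
    throw busz_error("domain: nPfd must be in 1..2^32-1");
  if (!(f > 0.0) || f > 1.0) throw busz_error("domain: f must be in (0, 1]");

  std::ifstream is = openIn(input);
  const BusHeader bush = readBusHeader(is);
  BuszParams p{bs, np, f};
  BuszHeaderFull h{bush, bs, np, (uint32_t)std::lround(f * 1000.0)};

  std::ofstream os = openOut(output);
  writeBuszHeader(os, h);

  std::vector<std::pair<uint64_t, uint64_t>> index;  // (first barcode, bytes)
  uint64_t nRecords = 0, nBlocks = 0, nonzeroPad = 0, bytesOut = 0;
  bool havePrev = false;
  BusRecord prev{0, 0, 0, 0, 0};
  std::vector<BusRecord> block;
  block.reserve(bs);

  auto flushBlock = [&]() {
    if (block.empty()) return;
    const std::vector<uint8_t> payload = compressBlock(block, p);
    wU32(os, (uint32_t)block.size());
    wU32(os, (uint32_t)payload.size());
    os.write((const char*)payload.data(), payload.size());
    index.emplace_back(block.front().barcode, payload.size());
    bytesOut += 8 + payload.size();
    ++nBlocks;
    block.clear();
  };

  BusRecord r;
  uint32_t pad;
  while (readRecord(is, r, pad)) {
    ++nRecords;
    if (pad != 0) ++nonzeroPad;
    if (r.ec < 0)
      throw busz_error("domain: negative EC at record " +
                       std::to_string(nRecords));
    if (r.count == 0)
      throw busz_error("domain: zero count at record " +
                       std::to_string(nRecords));
    if (havePrev && keyLess(r, prev))
      throw busz_error("not-sorted: record " + std::to_string(nRecords) +
                       " is out of order");
    prev = r;
    havePrev = true;
    block.push_back(r);
    if (block.size() == bs) flushBlock();
  }
  flushBlock();
  wU32(os, 0);  // terminator block header
  wU32(os, 0);
  os.flush();
  if (!os) throw busz_error("io: write failed for '" + output + "'");
  bytesOut += buszHeaderSize(h) + 8;

  if (writeIndex) {
    std::ofstream idx = openOut(indexPath);
    idx.write(kIdxMagic, 8);
    for (const auto& e : index) {
      wU64(idx, e.first);
      wU64(idx, e.second);
    }
    idx.flush();
    if (!idx) throw busz_error("io: write failed for '" + indexPath + "'");
  }

  const double bytesIn = fileSize(input);
  return List::create(
      _["records"] = (double)nRecords, _["blocks"] = (double)nBlocks,
      _["bytesIn"] = bytesIn, _["bytesOut"] = (double)bytesOut,
      _["ratio"] = bytesIn / (double)bytesOut,
      _["nonzeroPadding"] = (double)nonzeroPad);
}

// [[Rcpp::export]]
List cpp_decompress_file(std::string input, std::string output) {
  std::ifstream is = openIn(input);
  const BuszHeaderFull h = readBuszHeader(is);
  BuszParams p{h.blockSize, h.nPfd, h.fPpt / 1000.0};
  std::ofstream os = openOut(output);
  writeBusHeader(os, h.bus);
  uint64_t nRecords = 0, nBlocks = 0;
  for (;;) {
    uint32_t nRec, nBytes;
    if (!rU32(is, nRec) || !rU32(is, nBytes))
      throw busz_error("corruption: block " + std::to_string(nBlocks + 1) +
                       " header missing (no terminator?)");
    if (nRec == 0 && nBytes == 0) break;
    if (nRec == 0 || nRec > h.blockSize)
      throw busz_error("corruption: block " + std::to_string(nBlocks + 1) +
                       " has an invalid record count");
    std::vector<uint8_t> payload(nBytes);
    is.read((char*)payload.data(), nBytes);
    if ((uint32_t)is.gcount() != nBytes)
      throw busz_error("corruption: block " + std::to_string(nBlocks + 1) +
                       " is truncated");
    const std::vector<BusRecord> recs = decompressBlock(payload, nRec, p);
    for (const BusRecord& r : recs) writeRecord(os, r);
    nRecords += nRec;
    ++nBlocks;
  }
  os.flush();
  if (!os) throw busz_error("io: write failed for '" + output + "'");
  return List::create(
      _["records"] = (double)nRecords, _["blocks"] = (double)nBlocks,
      _["bytesIn"] = fileSize(input),
      _["bytesOut"] = (double)(busHeaderSize(h.bus) + 32.0 * nRecords));
}

// ------------------------------------------------------------------- lookup

// [[Rcpp::export]]
List cpp_lookup_barcode(std::string buszPath, std::string indexPath,
                        std::string barcode) {
  const uint64_t query = encodeSeq(barcode);

  // index: magic + fixed-width (first barcode u64, payload bytes u64) entries
  std::ifstream idx = openIn(indexPath);
  char magic[8];
  idx.read(magic, 8);
  if (idx.gcount() != 8 || std::memcmp(magic, kIdxMagic, 8) != 0)
    throw busz_error("format: not a BUSZ index file (bad magic)");
  std::vector<std::pair<uint64_t, uint64_t>> entries;
  uint64_t fb, nb;
  while (rU64(idx, fb)) {
    if (!rU64(idx, nb)) throw busz_error("truncated: index entry incomplete");
    if (!entries.empty() && fb < entries.back().first)
      throw busz_error("corruption: index first barcodes are not sorted");
    entries.emplace_back(fb, nb);
  }

  std::ifstream is = openIn(buszPath);
  const BuszHeaderFull h = readBuszHeader(is);
  if ((uint32_t)barcode.size() != h.bus.bcLen)
    throw busz_error("domain: query barcode length does not match the file");
  BuszParams p{h.blockSize, h.nPfd, h.fPpt / 1000.0};

  // offsets reconstructed from cumulative sums; integrity: total size must
  // equal header + sum(8 + payload) + terminator
  std::vector<uint64_t> offset(entries.size());
  uint64_t at = buszHeaderSize(h);
  for (size_t i = 0; i < entries.size(); ++i) {
    offset[i] = at;
    at += 8 + entries[i].second;
  }
  if ((double)(at + 8) != fileSize(buszPath))
    throw busz_error("integrity: index does not match the BUSZ file size");

  // candidate blocks: the last block starting strictly below the query plus
  // every block starting exactly at it (a barcode may straddle boundaries)
  std::vector<size_t> cand;
  for (size_t i = 0; i < entries.size(); ++i) {
    if (entries[i].first == query) cand.push_back(i);
  }
  size_t before = entries.size();
  for (size_t i = 0; i < entries.size(); ++i)
    if (entries[i].first < query) before = i;
  if (before != entries.size()) cand.insert(cand.begin(), before);

  std::vector<BusRecord> hits;
  for (size_t i : cand) {
    is.clear();
    is.seekg(offset[i]);
    uint32_t nRec, nBytes;
    if (!rU32(is, nRec) || !rU32(is, nBytes))
      throw busz_error("integrity: block header unreadable at index offset");
    if (nBytes != entries[i].second)
      throw busz_error("integrity: index block size disagrees with the file");
    std::vector<uint8_t> payload(nBytes);
    is.read((char*)payload.data(), nBytes);
    if ((uint32_t)is.gcount() != nBytes)
      throw busz_error("corruption: block " + std::to_string(i + 1) +
                       " is truncated");
    for (const BusRecord& r : decompressBlock(payload, nRec, p))
      if (r.barcode == query) hits.push_back(r);
  }
  return recordsToR(hits, h.bus);
}

// ------------------------------------------------------------------ inspect

// [[Rcpp::export]]
List cpp_inspect(std::string path) {
  std::ifstream probe = openIn(path);
  char magic[8] = {0};
  probe.read(magic, 8);
  probe.close();

  if (std::memcmp(magic, kBuszMagic, 8) == 0) {
    std::ifstream is = openIn(path);
    const BuszHeaderFull h = readBuszHeader(is);
    uint64_t nRecords = 0, nBlocks = 0;
    NumericVector colBytes(5);
    for (;;) {
      uint32_t nRec, nBytes;
      if (!rU32(is, nRec) || !rU32(is, nBytes))
        throw busz_error("corruption: block " + std::to_string(nBlocks + 1) +
                         " header missing (no terminator?)");
      if (nRec == 0 && nBytes == 0) break;
      std::vector<uint8_t> payload(nBytes);
      is.read((char*)payload.data(), nBytes);
      if ((uint32_t)is.gcount() != nBytes)
        throw busz_error("corruption: block " + std::to_string(nBlocks + 1) +
                         " is truncated");
      size_t at = 0;
      for (int c = 0; c < 5; ++c) {
        if (at + 4 > payload.size())
          throw busz_error("corruption: block payload truncated");
        uint32_t len = (uint32_t)payload[at] | ((uint32_t)payload[at + 1] << 8) |
                       ((uint32_t)payload[at + 2] << 16) |
                       ((uint32_t)payload[at + 3] << 24);
        at += 4 + len;
        if (at > payload.size())
          throw busz_error("corruption: column payload truncated");
        colBytes[c] += (double)len;
      }
      nRecords += nRec;
      ++nBlocks;
    }
    colBytes.attr("names") =
        CharacterVector::create("barcode", "umi", "ec", "count", "flags");
    return List::create(
        _["type"] = "busz", _["version"] = (double)h.bus.version,
        _["bcLen"] = (int)h.bus.bcLen, _["umiLen"] = (int)h.bus.umiLen,
        _["text"] = h.bus.text, _["blockSize"] = (double)h.blockSize,
        _["nPfd"] = (double)h.nPfd, _["f"] = h.fPpt / 1000.0,
        _["records"] = (double)nRecords, _["blocks"] = (double)nBlocks,
        _["columnBytes"] = colBytes, _["bytes"] = fileSize(path));
  }

  std::ifstream is = openIn(path);
  const BusHeader h = readBusHeader(is);  // throws format error if neither
  const double total = fileSize(path);
  const double payload = total - (double)busHeaderSize(h);
  if ((uint64_t)payload % 32 != 0)
    throw busz_error("truncated: BUS payload is not a multiple of 32 bytes");
  return List::create(_["type"] = "bus", _["version"] = (double)h.version,
                      _["bcLen"] = (int)h.bcLen, _["umiLen"] = (int)h.umiLen,
                      _["text"] = h.text, _["records"] = payload / 32.0,
                      _["bytes"] = total);
}
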