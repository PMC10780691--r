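// Arbitrary-precision modular arithmetic on top of OpenSSL BIGNUM.
// All big integers cross the R boundary as hex strings (lower/upper case
// accepted, optional leading '-'). Residue-class results are always
// non-negative; plain integer arithmetic (add/sub/mul) is signed.

#include <Rcpp.h>
#include <openssl/bn.h>
#include <openssl/rand.h>
#include <openssl/sha.h>
#include <stdexcept>
#include <string>

using namespace Rcpp;

namespace {

struct BnCtx {
  BN_CTX* ctx;
  BnCtx() : ctx(BN_CTX_new()) {
    if (!ctx) throw std::runtime_error("BN_CTX_new failed");
  }
  ~BnCtx() { BN_CTX_free(ctx); }
};

struct Bn {
  BIGNUM* p;
  Bn() : p(BN_new()) {
    if (!p) throw std::runtime_error("BN_new failed");
  }
  explicit Bn(const std::string& hex) : p(NULL) {
    if (!BN_hex2bn(&p, hex.c_str()))
      throw std::invalid_argument("invalid hex big integer: '" + hex + "'");
  }
  ~Bn() { BN_free(p); }
  Bn(const Bn&) = delete;
  Bn& operator=(const Bn&) = delete;
};

std::string to_hex(const BIGNUM* x) {
  char* h = BN_bn2hex(x);
  if (!h) throw std::runtime_error("BN_bn2hex failed");
  std::string out(h);
  OPENSSL_free(h);
  return out;
}

std::string to_dec(const BIGNUM* x) {
  char* d = BN_bn2dec(x);
  if (!d) throw std::runtime_error("BN_bn2dec failed");
  std::string out(d);
  OPENSSL_free(d);
  return out;
}

}  // namespace

// [[Rcpp::export(name = ".bn_add")]]
std::string bn_add_(std::string a, std::string b) {
  Bn A(a), B(b), R;
  if (!BN_add(R.p, A.p, B.p)) stop("BN_add failed");
  return to_hex(R.p);
}

// [[Rcpp::export(name = ".bn_sub")]]
std::string bn_sub_(std::string a, std::string b) {
  Bn A(a), B(b), R;
  if (!BN_sub(R.p, A.p, B.p)) stop("BN_sub failed");
  return to_hex(R.p);
}

// [[Rcpp::export(name = ".bn_mul")]]
std::string bn_mul_(std::string a, std::string b) {
  BnCtx c;
  Bn A(a), B(b), R;
  if (!BN_mul(R.p, A.p, B.p, c.ctx)) stop("BN_mul failed");
  return to_hex(R.p);
}

// Integer quotient, truncated toward zero (used for the Paillier L function,
// where the division is exact by construction).
// [[Rcpp::export(name = ".bn_div")]]
std::string bn_div_(std::string a, std::string b) {
  BnCtx c;
  Bn A(a), B(b), Q, R;
  if (BN_is_zero(B.p)) stop("division by zero");
  if (!BN_div(Q.p, R.p, A.p, B.p, c.ctx)) stop("BN_div failed");
  return to_hex(Q.p);
}

// Non-negative residue a mod m.
// [[Rcpp::export(name = ".bn_mod")]]
std::string bn_mod_(std::string a, std::string m) {
  BnCtx c;
  Bn A(a), M(m), R;
  if (!BN_nnmod(R.p, A.p, M.p, c.ctx)) stop("BN_nnmod failed");
  return to_hex(R.p);
}

// [[Rcpp::export(name = ".bn_mod_mul")]]
std::string bn_mod_mul_(std::string a, std::string b, std::string m) {
  BnCtx c;
  Bn A(a), B(b), M(m), R;
  if (!BN_mod_mul(R.p, A.p, B.p, M.p, c.ctx)) stop("BN_mod_mul failed");
  return to_hex(R.p);
}

// [[Rcpp::export(name = ".bn_mod_exp")]]
std::string bn_mod_exp_(std::string a, std::string e, std::string m) {
  BnCtx c;
  Bn A(a), E(e), M(m), R, An;
  if (BN_is_negative(E.p)) stop("negative exponent not supported");
  if (!BN_nnmod(An.p, A.p, M.p, c.ctx)) stop("BN_nnmod failed");
  if (!BN_mod_exp(R.p, An.p, E.p, M.p, c.ctx)) stop("BN_mod_exp failed");
  return to_hex(R.p);
}

// [[Rcpp::export(name = ".bn_mod_inverse")]]
std::string bn_mod_inverse_(std::string a, std::string m) {
  BnCtx c;
  Bn A(a), M(m), R;
  if (!BN_mod_inverse(R.p, A.p, M.p, c.ctx))
    stop("no modular inverse exists");
  return to_hex(R.p);
}

// [[Rcpp::export(name = ".bn_gcd")]]
std::string bn_gcd_(std::string a, std::string b) {
  BnCtx c;
  Bn A(a), B(b), R;
  BN_set_negative(A.p, 0);
  BN_set_negative(B.p, 0);
  if (!BN_gcd(R.p, A.p, B.p, c.ctx)) stop("BN_gcd failed");
  return to_hex(R.p);
}

// [[Rcpp::export(name = ".bn_cmp")]]
int bn_cmp_(std::string a, std::string b) {
  Bn A(a), B(b);
  return BN_cmp(A.p, B.p);
}

// [[Rcpp::export(name = ".bn_bits")]]
int bn_bits_(std::string a) {
  Bn A(a);
  return BN_num_bits(A.p);
}

// [[Rcpp::export(name = ".bn_is_prime")]]
bool bn_is_prime_(std::string a) {
  BnCtx c;
  Bn A(a);
#if OPENSSL_VERSION_NUMBER >= 0x30000000L
  int r = BN_check_prime(A.p, c.ctx, NULL);
#else
  int r = BN_is_prime_ex(A.p, BN_prime_checks, c.ctx, NULL);
#endif
  if (r < 0) stop("primality test failed");
  return r == 1;
}

// [[Rcpp::export(name = ".bn_to_dec")]]
std::string bn_to_dec_(std::string a) {
  Bn A(a);
  return to_dec(A.p);
}

// [[Rcpp::export(name = ".bn_from_dec")]]
std::string bn_from_dec_(std::string a) {
  BIGNUM* p = NULL;
  if (!BN_dec2bn(&p, a.c_str()))
    stop("invalid decimal big integer");
  std::string out = to_hex(p);
  BN_free(p);
  return out;
}

// Build an odd candidate of exactly `bits` bits from caller-supplied entropy
// (top and bottom bits forced). The caller chooses the entropy source, which
// keeps prime generation seedable for reproducible test keys.
// [[Rcpp::export(name = ".bn_candidate_from_bytes")]]
std::string bn_candidate_from_bytes_(RawVector bytes, int bits) {
  if (bits < 2) stop("bits must be >= 2");
  Bn A;
  if (!BN_bin2bn(RAW(bytes), bytes.size(), A.p)) stop("BN_bin2bn failed");
  if (!BN_mask_bits(A.p, bits)) {
    // candidate shorter than `bits`: masking is a no-op failure; fall through
  }
  BN_set_bit(A.p, bits - 1);
  BN_set_bit(A.p, 0);
  return to_hex(A.p);
}

// Raw big-endian bytes -> big integer, no bit forcing.
// [[Rcpp::export(name = ".bn_from_bytes")]]
std::string bn_from_bytes_(RawVector bytes) {
  Bn A;
  if (!BN_bin2bn(RAW(bytes), bytes.size(), A.p)) stop("BN_bin2bn failed");
  return to_hex(A.p);
}

// Cryptographic entropy from the OS (OpenSSL RAND), for production keys and
// encryption randomizers when no reproducibility seed is requested.
// [[Rcpp::export(name = ".crypto_rand_bytes")]]
RawVector crypto_rand_bytes_(int n) {
  RawVector out(n);
  if (RAND_bytes(RAW(out), n) != 1) stop("RAND_bytes failed");
  return out;
}

// [[Rcpp::export(name = ".sha256_hex")]]
std::string sha256_hex_(std::string s) {
  unsigned char md[SHA256_DIGEST_LENGTH];
  SHA256(reinterpret_cast<const unsigned char*>(s.c_str()), s.size(), md);
  static const char* hexd = "0123456789abcdef";
  std::string out;
  out.reserve(2 * SHA256_DIGEST_LENGTH);
  for (int i = 0; i < SHA256_DIGEST_LENGTH; ++i) {
    out.push_back(hexd[md[i] >> 4]);
    out.push_back(hexd[md[i] & 0x0f]);
  }
  return out;
}

// ---- Vectorized Paillier kernels ------------------------------------------
// These only batch the per-element modular arithmetic; key handling, encoding
// and the protection-scheme logic live in R.

// c_i = g^{m_i} r_i^n mod n^2, with g = n + 1 so that
// g^m = 1 + m n (mod n^2); the binomial identity makes this exact.
// [[Rcpp::export(name = ".paillier_encrypt_vec")]]
CharacterVector paillier_encrypt_vec_(std::string n_hex, std::string nsq_hex,
                                      CharacterVector m_hex,
                                      CharacterVector r_hex) {
  BnCtx c;
  Bn N(n_hex), NSQ(nsq_hex);
  int len = m_hex.size();
  if (r_hex.size() != len) stop("m and r length mismatch");
  CharacterVector out(len);
  Bn M, RN, G, T;
  for (int i = 0; i < len; ++i) {
    Bn Mi(as<std::string>(m_hex[i])), Ri(as<std::string>(r_hex[i]));
    // g^m = 1 + m*n mod n^2
    if (!BN_mod_mul(T.p, Mi.p, N.p, NSQ.p, c.ctx)) stop("BN_mod_mul failed");
    if (!BN_add_word(T.p, 1)) stop("BN_add_word failed");
    if (!BN_nnmod(G.p, T.p, NSQ.p, c.ctx)) stop("BN_nnmod failed");
    if (!BN_mod_exp(RN.p, Ri.p, N.p, NSQ.p, c.ctx)) stop("BN_mod_exp failed");
    if (!BN_mod_mul(T.p, G.p, RN.p, NSQ.p, c.ctx)) stop("BN_mod_mul failed");
    out[i] = to_hex(T.p);
  }
  return out;
}

// m_i = L(c_i^lambda mod n^2) * mu mod n, L(x) = (x - 1) / n.
// [[Rcpp::export(name = ".paillier_decrypt_vec")]]
CharacterVector paillier_decrypt_vec_(std::string n_hex, std::string nsq_hex,
                                      std::string lam_hex, std::string mu_hex,
                                      CharacterVector c_hex) {
  BnCtx c;
  Bn N(n_hex), NSQ(nsq_hex), LAM(lam_hex), MU(mu_hex);
  int len = c_hex.size();
  CharacterVector out(len);
  Bn T, Q, R;
  for (int i = 0; i < len; ++i) {
    Bn Ci(as<std::string>(c_hex[i]));
    if (!BN_mod_exp(T.p, Ci.p, LAM.p, NSQ.p, c.ctx)) stop("BN_mod_exp failed");
    if (!BN_sub_word(T.p, 1)) stop("BN_sub_word failed");
    if (!BN_div(Q.p, R.p, T.p, N.p, c.ctx)) stop("BN_div failed");
    if (!BN_mod_mul(T.p, Q.p, MU.p, N.p, c.ctx)) stop("BN_mod_mul failed");
    out[i] = to_hex(T.p);
  }
  return out;
}

// Encrypted-domain projection: y_k = prod_i c_i^{E[i,k]} mod n^2, where E
// holds the (mod-n reduced, hence non-negative) quantized matrix mantissas.
// [[Rcpp::export(name = ".paillier_project_vec")]]
CharacterVector paillier_project_vec_(std::string nsq_hex,
                                      CharacterVector c_hex,
                                      CharacterMatrix exp_hex) {
  BnCtx c;
  Bn NSQ(nsq_hex);
  int j = c_hex.size();
  if (exp_hex.nrow() != j) stop("ciphertext / matrix dimension mismatch");
  int q = exp_hex.ncol();

  // Pre-parse ciphertexts once.
  std::vector<BIGNUM*> cts(j);
  for (int i = 0; i < j; ++i) {
    cts[i] = NULL;
    std::string h = as<std::string>(c_hex[i]);
    if (!BN_hex2bn(&cts[i], h.c_str())) {
      for (int u = 0; u <= i; ++u) BN_free(cts[u]);
      stop("invalid ciphertext hex");
    }
  }
  CharacterVector out(q);
  Bn ACC, P, E;
  for (int k = 0; k < q; ++k) {
    BN_one(ACC.p);
    for (int i = 0; i < j; ++i) {
      std::string h = as<std::string>(exp_hex(i, k));
      BIGNUM* e = NULL;
      if (!BN_hex2bn(&e, h.c_str())) {
        for (int u = 0; u < j; ++u) BN_free(cts[u]);
        stop("invalid exponent hex");
      }
      int ok = BN_mod_exp(P.p, cts[i], e, NSQ.p, c.ctx) &&
               BN_mod_mul(ACC.p, ACC.p, P.p, NSQ.p, c.ctx);
      BN_free(e);
      if (!ok) {
        for (int u = 0; u < j; ++u) BN_free(cts[u]);
        stop("modular arithmetic failed");
      }
    }
    out[k] = to_hex(ACC.p);
  }
  for (int u = 0; u < j; ++u) BN_free(cts[u]);
  return out;
}

// Frame-batched encrypted projection: rows of ct_mat are per-frame
// ciphertext vectors (T x j); the exponent matrix (j x q) is parsed once.
// Returns the T x q matrix of projected ciphertexts.
// [[Rcpp::export(name = ".paillier_project_mat")]]
CharacterMatrix paillier_project_mat_(std::string nsq_hex,
                                      CharacterMatrix ct_mat,
                                      CharacterMatrix exp_hex) {
  BnCtx c;
  Bn NSQ(nsq_hex);
  int T = ct_mat.nrow(), j = ct_mat.ncol();
  if (exp_hex.nrow() != j) stop("ciphertext / matrix dimension mismatch");
  int q = exp_hex.ncol();
  std::vector<BIGNUM*> exps(static_cast<size_t>(j) * q, (BIGNUM*)NULL);
  auto cleanup_exps = [&]() {
    for (auto e : exps)
      if (e) BN_free(e);
  };
  for (int i = 0; i < j; ++i)
    for (int k = 0; k < q; ++k) {
      std::string h = as<std::string>(exp_hex(i, k));
      if (!BN_hex2bn(&exps[static_cast<size_t>(i) * q + k], h.c_str())) {
        cleanup_exps();
        stop("invalid exponent hex");
      }
    }
  CharacterMatrix out(T, q);
  Bn ACC, P, CT;
  for (int t = 0; t < T; ++t) {
    std::vector<BIGNUM*> row(j, (BIGNUM*)NULL);
    bool ok = true;
    for (int i = 0; i < j && ok; ++i) {
      std::string h = as<std::string>(ct_mat(t, i));
      if (!BN_hex2bn(&row[i], h.c_str())) ok = false;
    }
    if (!ok) {
      for (auto r : row)
        if (r) BN_free(r);
      cleanup_exps();
      stop("invalid ciphertext hex");
    }
    for (int k = 0; k < q && ok; ++k) {
      BN_one(ACC.p);
      for (int i = 0; i < j && ok; ++i) {
        ok = BN_mod_exp(P.p, row[i], exps[static_cast<size_t>(i) * q + k],
                        NSQ.p, c.ctx) &&
             BN_mod_mul(ACC.p, ACC.p, P.p, NSQ.p, c.ctx);
      }
      if (ok) out(t, k) = to_hex(ACC.p);
    }
    for (auto r : row)
      if (r) BN_free(r);
    if (!ok) {
      cleanup_exps();
      stop("modular arithmetic failed");
    }
  }
  cleanup_exps();
  return out;
}

// Exact big-integer matrix-vector product of signed mantissas (no modulus):
// y_k = sum_i x_i * M[i,k]. Used as the plaintext-side reference for the
// encrypted projection.
// [[Rcpp::export(name = ".bn_matvec")]]
CharacterVector bn_matvec_(CharacterVector x_hex, CharacterMatrix m_hex) {
  BnCtx c;
  int j = x_hex.size();
  if (m_hex.nrow() != j) stop("dimension mismatch");
  int q = m_hex.ncol();
  CharacterVector out(q);
  Bn ACC, P;
  for (int k = 0; k < q; ++k) {
    BN_zero(ACC.p);
    for (int i = 0; i < j; ++i) {
      Bn Xi(as<std::string>(x_hex[i])), Mik(as<std::string>(m_hex(i, k)));
      if (!BN_mul(P.p, Xi.p, Mik.p, c.ctx)) stop("BN_mul failed");
      if (!BN_add(ACC.p, ACC.p, P.p)) stop("BN_add failed");
    }
    out[k] = to_hex(ACC.p);
  }
  return out;
}
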