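{"id_str":"t001","user":{"id_str":"u1"},"retweeted_status":{"user":{"id_str":"u2"}},"entities":{"user_mentions":[{"id_str":"u2"}],"urls":[]},"text":"rt"}
{"id_str":"t002","user":{"id_str":"u1"},"retweeted_status":{"user":{"id_str":"u2"}},"entities":{"user_mentions":[{"id_str":"u2"}],"urls":[]},"text":"rt"}
{"id_str":"t003","user":{"id_str":"u1"},"retweeted_status":{"user":{"id_str":"u3"}},"entities":{"user_mentions":[{"id_str":"u3"}],"urls":[]},"text":"rt"}
{"id_str":"t004","user":{"id_str":"u2"},"retweeted_status":{"user":{"id_str":"u1"}},"entities":{"user_mentions":[{"id_str":"u1"}],"urls":[]},"text":"rt"}
{"id_str":"t005","user":{"id_str":"u2"},"retweeted_status":{"user":{"id_str":"u1"}},"entities":{"user_mentions":[{"id_str":"u1"}],"urls":[]},"text":"rt"}
{"id_str":"t006","user":{"id_str":"u3"},"retweeted_status":{"user":{"id_str":"u1"}},"entities":{"user_mentions":[{"id_str":"u1"}],"urls":[]},"text":"rt"}
{"id_str":"t007","user":{"id_str":"u3"},"retweeted_status":{"user":{"id_str":"u1"}},"entities":{"user_mentions":[{"id_str":"u1"}],"urls":[]},"text":"rt"}
{"id_str":"t008","user":{"id_str":"u4"},"retweeted_status":{"user":{"id_str":"u1"}},"entities":{"user_mentions":[{"id_str":"u1"}],"urls":[]},"text":"rt"}
{"id_str":"t009","user":{"id_str":"u4"},"retweeted_status":{"user":{"id_str":"u1"}},"entities":{"user_mentions":[{"id_str":"u1"}],"urls":[]},"text":"rt"}
{"id_str":"t010","user":{"id_str":"u5"},"retweeted_status":{"user":{"id_str":"u1"}},"entities":{"user_mentions":[{"id_str":"u1"}],"urls":[]},"text":"rt"}
{"id_str":"t011","user":{"id_str":"u1"},"retweeted_status":{"user":{"id_str":"u3"}},"entities":{"user_mentions":[{"id_str":"u3"}],"urls":[]},"text":"rt"}
{"id_str":"t012","user":{"id_str":"u6"},"retweeted_status":{"user":{"id_str":"u5"}},"entities":{"user_mentions":[{"id_str":"u5"}],"urls":[]},"text":"rt"}
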