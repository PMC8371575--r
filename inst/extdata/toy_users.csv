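user_id,profile_text,followers,verified,location,bot_score
u1,likes politics,100,TRUE,"New York, NY",0.1
u2,sports fan,50,FALSE,"Los Angeles, CA",0.2
u3,news junkie,80,FALSE,"Chicago, IL",0.3
u4,always posting,10,FALSE,"Houston, TX",0.8
u5,quiet,5,FALSE,"Miami, FL",0.4
u6,lurker,2,FALSE,"Seattle, WA",0.5
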