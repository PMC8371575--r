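handle,domains,bias
synthleftdaily,leftdaily.example,1
synthleanleft,leanleft.example,2
synthcenterwire,centerwire.example,3
synthleanright,leanright.example,4
synthrightpost,rightpost.example;rightpost-news.example,5
synthfarright,farright.example,5
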