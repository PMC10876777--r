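{"participant_id":"PCA_001","group":"PCA","task":"picture","words":[{"word":"there","start":0,"end":0.312623662928793,"lemma":"there","upos":"PRON","deprel":"expl"},{"word":"be","start":0.771184929693416,"end":1.08380859262221,"lemma":"be","upos":"AUX","deprel":"root"},{"word":"on","start":1.20216064806896,"end":1.51478431099775,"lemma":"on","upos":"ADP","deprel":"case"},{"word":"the","start":2.62389777631931,"end":2.9365214392481,"lemma":"the","upos":"DET","deprel":"det"},{"word":"woman","start":3.27383248587738,"end":3.89907981173497,"lemma":"woman","upos":"NOUN","deprel":"obj"},{"word":"the","start":5.17508607396644,"end":5.48770973689523,"lemma":"the","upos":"DET","deprel":"det"},{"word":"bird","start":5.6282626188918,"end":5.94088628182059,"lemma":"bird","upos":"NOUN","deprel":"obj"},{"word":"the","start":6.11235472519877,"end":6.42497838812756,"lemma":"the","upos":"DET","deprel":"det"},{"word":"sailboat","start":6.71595926689507,"end":7.34120659275266,"lemma":"sailboat","upos":"NOUN","deprel":"obj"},{"word":"the","start":7.38559910997148,"end":7.69822277290027,"lemma":"the","upos":"DET","deprel":"det"},{"word":"in","start":8.42383300549951,"end":8.7364566684283,"lemma":"in","upos":"ADP","deprel":"case"},{"word":"blanket","start":9.0717898468687,"end":9.69703717272628,"lemma":"blanket","upos":"NOUN","deprel":"obj"},{"word":"the","start":11.4014072697379,"end":11.7140309326667,"lemma":"the","upos":"DET","deprel":"det"},{"word":"radio","start":11.9073460909668,"end":12.5325934168243,"lemma":"radio","upos":"NOUN","deprel":"obj"},{"word":"the","start":12.5709148690226,"end":12.8835385319514,"lemma":"the","upos":"DET","deprel":"det"},{"word":"w0906","start":13.0023507674057,"end":13.3149744303345,"lemma":"w0906","upos":"NOUN","deprel":"obj"},{"word":"the","start":13.365107984534,"end":13.6777316474628,"lemma":"the","upos":"DET","deprel":"det"},{"word":"w0906","start":13.6941186221131,"end":14.0067422850419,"lemma":"w0906","upos":"NOUN","deprel":"obj"},{"word":"under","start":15.500493416802,"end":16.1257407426596,"lemma":"under","upos":"ADP","deprel":"case"},{"word":"the","start":16.3117441972933,"end":16.6243678602221,"lemma":"the","upos":"DET","deprel":"det"},{"word":"w0906","start":17.0994011717958,"end":17.4120248347246,"lemma":"w0906","upos":"NOUN","deprel":"obj"},{"word":"the","start":17.6130726668544,"end":17.9256963297832,"lemma":"the","upos":"DET","deprel":"det"},{"word":"w0906","start":18.0298177504471,"end":18.3424414133758,"lemma":"w0906","upos":"NOUN","deprel":"obj"},{"word":"the","start":18.3890685851257,"end":18.7016922480545,"lemma":"the","upos":"DET","deprel":"det"},{"word":"w0906","start":19.2722391523173,"end":19.5848628152461,"lemma":"w0906","upos":"NOUN","deprel":"obj"},{"word":"the","start":20.2771313698495,"end":20.5897550327783,"lemma":"the","upos":"DET","deprel":"det"},{"word":"near","start":20.6063610098956,"end":20.9189846728244,"lemma":"near","upos":"ADP","deprel":"case"},{"word":"w0906","start":21.0745081221783,"end":21.3871317851071,"lemma":"w0906","upos":"NOUN","deprel":"obj"},{"word":"the","start":21.4937325757483,"end":21.8063562386771,"lemma":"the","upos":"DET","deprel":"det"},{"word":"w0906","start":22.180590031816,"end":22.4932136947448,"lemma":"w0906","upos":"NOUN","deprel":"obj"},{"word":"the","start":23.6761933794469,"end":23.9888170423757,"lemma":"the","upos":"DET","deprel":"det"},{"word":"w0906","start":24.4933714900241,"end":24.8059951529528,"lemma":"w0906","upos":"NOUN","deprel":"obj"},{"word":"the","start":24.8828272649805,"end":25.1954509279093,"lemma":"the","upos":"DET","deprel":"det"},{"word":"w0906","start":25.330596207055,"end":25.6432198699838,"lemma":"w0906","upos":"NOUN","deprel":"obj"},{"word":"by","start":25.7911070798616,"end":26.1037307427904,"lemma":"by","upos":"ADP","deprel":"case"},{"word":"the","start":26.5744452755453,"end":26.8870689384741,"lemma":"the","upos":"DET","deprel":"det"},{"word":"w0906","start":27.3735115940589,"end":27.6861352569877,"lemma":"w0906","upos":"NOUN","deprel":"obj"},{"word":"the","start":27.8083411149624,"end":28.1209647778912,"lemma":"the","upos":"DET","deprel":"det"},{"word":"w0906","start":29.6447529976903,"end":29.9573766606191,"lemma":"w0906","upos":"NOUN","deprel":"obj"},{"word":"the","start":30.2645107499262,"end":30.577134412855,"lemma":"the","upos":"DET","deprel":"det"},{"word":"w0906","start":30.6377114760256,"end":30.9503351389544,"lemma":"w0906","upos":"NOUN","deprel":"obj"},{"word":"the","start":31.9386342368592,"end":32.251257899788,"lemma":"the","upos":"DET","deprel":"det"},{"word":"over","start":32.3416681657966,"end":32.9669154916541,"lemma":"over","upos":"ADP","deprel":"case"},{"word":"w0906","start":33.7700440643129,"end":34.0826677272417,"lemma":"w0906","upos":"NOUN","deprel":"obj"}]}
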